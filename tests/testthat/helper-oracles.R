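# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Brute-force residue tally by regex counting, one residue at a time.
tally_oracle <- function(res_string, alphabet) {
  vapply(alphabet, function(ch) {
    hits <- gregexpr(ch, res_string, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }, integer(1))
}

# Closed-form simple-linear-regression coefficients and R-squared.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- stats::cor(x, y)^2
  c(intercept = a, slope = b, r2 = r2)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments (no ties assumed).
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  pl <- mean(all_u <= u_obs)
  pg <- mean(all_u >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(pl, pg)))
}

# Random RNA / protein residue strings.
random_rna <- function(n) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE), collapse = "")
}
random_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
# Random in-frame coding RNA: AUG + non-stop codons + UAA.
random_cds <- function(n_codons) {
  codons <- c()
  repeat {
    cand <- random_rna(3)
    if (!cand %in% c("UAA", "UAG", "UGA")) codons <- c(codons, cand)
    if (length(codons) == n_codons) break
  }
  paste0("AUG", paste(codons, collapse = ""), "UAA")
}
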