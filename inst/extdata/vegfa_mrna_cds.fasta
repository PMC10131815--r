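>VEGFA165_CDS coding sequence of human VEGF-A 165, 576 nt incl. start and stop
AUGAACUUUCUGCUGUCUUGGGUGCAUUGGAGCCUUGCCUUGCUGCUCUACCUCCACCAU
GCCAAGUGGUCCCAGGCUGCACCCAUGGCAGAAGGAGGAGGGCAGAAUCAUCACGAAGUG
GUGAAGUUCAUGGAUGUCUAUCAGCGCAGCUACUGCCAUCCAAUCGAGACCCUGGUGGAC
AUCUUCCAGGAGUACCCUGAUGAGAUCGAGUACAUCUUCAAGCCAUCCUGUGUGCCCCUG
AUGCGAUGCGGGGGCUGCUGCAAUGACGAGGGCCUGGAGUGUGUGCCCACUGAGGAGUCC
AACAUCACCAUGCAGAUUAUGCGGAUCAAACCUCACCAAGGCCAGCACAUAGGAGAGAUG
AGCUUCCUACAGCACAACAAAUGUGAAUGCAGACCAAAGAAAGAUAGAGCAAGACAAGAA
AAUCCCUGUGGGCCUUGCUCAGAGCGGAGAAAGCAUUUGUUUGUACAAGAUCCGCAGACG
UGUAAAUGUUCCUGCAAAAACACAGACUCGCGUUGCAAGGCGAGGCAGCUUGAGUUAAAC
GAACGUACUUGCAGAUGUGACAAGCCGAGGCGGUGA
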