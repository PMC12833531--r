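>synthetic_car example CAR-scale construct (synthetic stand-in, 2 planted slippery sites)
AUGAGGGUAGCUCCCUUAUUAGCCUUCUGCUCGUCGCUGGAAAGGAGCUACAUAGGUCGACCGCUUGUGUUCCGGCCUGA
CCGGCCAUAUCGGGCGCCCCAAAGACACAACUUCACGCUUCGGAUAACGGCCCCCUUAUUGAAUCCUCAGCAAGCGGCGA
UCAUUGUCCAACAUAAAAACGUAGAAACAAACCUCAGAACCGUGUGCGGUCCGGUCGCAGGCAGGAGGCUAACGAGAGUG
GCUCCAAUCGGCGUGUCCUACAAUUGGGAUCCUAUAGUGGGAUCGUGCUCCACCCGCGCCCGAUCCACCAUAAUGACGGA
GAGUCGACGGGCCGGCGAUGGAGCUAUGCAAAGAGCCUAUGCUGGCCUCAUAACACUGCUAGCUGCAUCUCCUUCCUUUG
GCUAUUGGCUUCGUAUGAGGGUGAGGACGUCAGCACGAGAUCUUGCAUUUCCGAGGCCAGUUGUGCAUACGUACCCCCCG
ACGUUCUUAGGGGAAACGUGUCCGAAUGCGCGUAAUCGCCUCAGUGUGUUGCCUCGGUGUCGUUUAGCUUAUCAUGCCUU
CCGCCUACCGCCGCGCAGCAAUCCCCAGUCCUCCAGGGUCCGGUACUGUAAGAAUGGAAUGCUGUCCUCCCUGAUACACA
UGAUCAUAGGGCCUGCGCCAGGUCCCAUUGUGGACAUCUACGUUGACGUAAUGAUCCCUAGUCGUACACUCCGUGGUGGU
UGCAGUGCAUCGCUAUAUUAUCCUCACCGGCCAGUACCGCUCGGGGAUGCGGGCACGGGCUCACUAGGGUCACCACAAAU
CGGCUCUACACGUACAGUUUACACGCAUCAGAUACUGCCGCUGACGAAUCUUCUUGGUAAACGUGCUCAUCCACUCUGGC
UACAGGUAAGCGGUCCGCCCCAGUUCGACACCACAGAAGGGUCCUCUAGUGGGCGCCGACAUCGGAUCGGGAAGCGACUA
AGGUGUCCCCUCCGCGUGGGUUCACUCAAAGCGAGGAGAAUAGUGGCGGGGCGCGCUUUCCAAAGAUACUUGGCGCACCC
AAACGUUAGGCGACUCGAGGUGACAAGGCAAUUGAAGGGGUCUCGGUCCCGCGCGUGUCUGGCCGGGGUAGGCACAGCGC
ACUGUUCUCUUCUCAAAUCUGGGCGCGACUGCGUCCGCAAGGUGCGUAGACUAGAAACGUGGCCCGGUGCCUCCUACCUG
GAAAACGCUCCCGGCAAAUUCGAGCCUCCCCAAUGUGUACGACCGCCAUGUACUACCGAGUUGUACGCGGCAUCUUAUGC
CCCGGCUUCGGGGAUCGUUACAUGGCGCUUCGCCAGAUAUCAGUGUUCCGAAUCGGGUUCUAAUUCGCGUGGUAUCCUAU
GCCGGCAAUUCCCAAUAAUAUCAUUAGCGGGCGACGUCGAAGACCUAGGCCGACGGCGAACGCCGUCUUUGCGUGGCGUC
UUCUGCGAAAAACAUACACAGGUAGACUAA
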