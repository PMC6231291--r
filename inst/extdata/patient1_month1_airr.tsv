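v_call	j_call	junction	junction_aa	duplicate_count
TRBV10-1*01	TRBJ1-4	TGCCGCTCTAGCACAACCCGTCTGAGCCTGGGCAACTATGAACTGGACGTCTTC	CRSSTTRLSLGNYELDVF	10
TRBV10-1*01	TRBJ2-7	TGCAAGGTAATCATTGACACTGAAGCATACGGTGAGAAATTC	CKVIIDTEAYGEKF	10
TRBV11-1*01	TRBJ1-3	TGCAATATGGGAAGTTCAGATACCGAGAGGCCTACAGTATTC	CNMGSSDTERPTVF	6
TRBV11-1*01	TRBJ2-1	TGCCCGTCGAGCAGGAGGGGGATTGAGGTTAGCACGGGGCATTCCTTC	CPSSRRGIEVSTGHSF	8
TRBV11-1*01	TRBJ2-5	TGCCCGTTTCGCGGTTATATACAACGCTACCTACGGGTGCCCCAATTC	CPFRGYIQRYLRVPQF	10
TRBV11-1*01	TRBJ2-5	TGCGCTGGACTTGAAGTCAAGGCCCGGCTTGACGGACATTTC	CAGLEVKARLDGHF	17
TRBV12-1*01	TRBJ1-5	TGCCAGGGAGCAGTCTTTTGGGGCATGAATTGGAACTTC	CQGAVFWGMNWNF	7
TRBV12-1*01	TRBJ2-5	TGCACGTCCAAGCGTGTCTGCAGGGAGAAAGGTCCACTCTCTAGTCCCTTC	CTSKRVCREKGPLSSPF	149
TRBV14-1*01	TRBJ1-1	TGCTGCGAGCCGCTCTCACTCGTAGAGTCATATCGATTTTTC	CCEPLSLVESYRFF	15
TRBV14-1*01	TRBJ2-3	TGCGTGACAAGCAAAGACTTTTGTAGTGAGCCTTTATGGCGGTTC	CVTSKDFCSEPLWRF	10
TRBV15-1*01	TRBJ1-4	TGCGGCTATTCTCGACACCGCCTCTTAAACCAAACTTGTTCACTATTC	CGYSRHRLLNQTCSLF	11
TRBV15-1*01	TRBJ1-5	TGCAACTGGGCCCCCTCCACACTTACCCAAGGTTTC	CNWAPSTLTQGF	10
TRBV15-1*01	TRBJ1-5	TGCGATCGTGGGACTAATTTGTTTCATAACGAGCTCCCGTGGCTGAGATTC	CDRGTNLFHNELPWLRF	11
TRBV15-1*01	TRBJ2-2	TGCCGTCTTAGCTCCCCACAGACCCAGTTC	CRLSSPQTQF	14
TRBV15-1*01	TRBJ2-5	TGCGATAACGCGCGAGTACTAGACGTACTTAACGCGTTC	CDNARVLDVLNAF	11
TRBV18-1*01	TRBJ1-4	TGCAACATTACTAAAACCGGGCAATCACCCGATCGGGCCCATTCACCCCCTTTC	CNITKTGQSPDRAHSPPF	17
TRBV18-1*01	TRBJ1-4	TGCGTGGATATAAATGGGTATTGGTCTAAGATATATTTC	CVDINGYWSKIYF	11
TRBV18-1*01	TRBJ2-5	TGCGTGAATGACTGTTTCGGGCTGCGCCCTACACCCAGGTGCGGCTTC	CVNDCFGLRPTPRCGF	11
TRBV18-1*01	TRBJ2-6	TGCATGCGTCTGAGTGTTGAGTCGAAAACTACATCTCTGTTTCGAGAATACTTC	CMRLSVESKTTSLFREYF	15
TRBV19-1*01	TRBJ2-6	TGCTGGCGATTCCTGGTGCTATTTCTACGGTACCACATCGAATTC	CWRFLVLFLRYHIEF	10
TRBV2-1*01	TRBJ1-6	TGCACCGTGCTACAATCTCGACACTCTCTTCGGATACTCGGTTGGTTC	CTVLQSRHSLRILGWF	9
TRBV2-1*01	TRBJ2-3	TGCAGACACAGAGAGCAAAGCGGACGCCTGGGGCGTTGTCAATTC	CRHREQSGRLGRCQF	10
TRBV2-1*01	TRBJ2-3	TGCTCAATGCCCTTACAAGGCATTAAGCGCTTCGATCTGCCTTTTTTC	CSMPLQGIKRFDLPFF	13
TRBV20-1*01	TRBJ1-2	TGCAATTTACTTGCCTCCTCAAGATCGGCGCGTGGGAAGCACGCGTTC	CNLLASSRSARGKHAF	12
TRBV20-1*01	TRBJ1-2	TGCCATGTTTTCGCGATAGGAGAGCAAGTTCCGTGCTCTAAAGGTGCTTTC	CHVFAIGEQVPCSKGAF	15
TRBV20-1*01	TRBJ1-3	TGCACCCAAAAGGCTGTTACAAACTGCGCGTCTAGATATACCCGCTTC	CTQKAVTNCASRYTRF	13
TRBV20-1*01	TRBJ2-2	TGCCGACTGATTCGTGTTGCCACAGGTAGCCCGCAACACCCCGCAAAGAAATTC	CRLIRVATGSPQHPAKKF	168
TRBV24-1*01	TRBJ1-3	TGCGATCGTATGATGGCTAATTATCATCTGTGTCCTAACCCGCGATTC	CDRMMANYHLCPNPRF	9
TRBV24-1*01	TRBJ1-4	TGCAGCGCAAATGTGATTCCTCGTACAGTAAATGACACGTCGACTTTC	CSANVIPRTVNDTSTF	13
TRBV24-1*01	TRBJ2-1	TGCGAAACTTTGCACGAATGTTTCTCCTACGAGAACGTGCTTGCCCGGGAGTTC	CETLHECFSYENVLAREF	17
TRBV25-1*01	TRBJ1-1	TGCAGGACACTAGGTCACCGATTGGCTAATAACTTTACGCTGCTTTTCGCGTTC	CRTLGHRLANNFTLLFAF	13
TRBV25-1*01	TRBJ1-4	TGCTCACCCACAATTGACATTATGCTCTATATGCATGCTCTAACTTTC	CSPTIDIMLYMHALTF	12
TRBV25-1*01	TRBJ1-5	TGCATGTTAAACGTTCACATAAGATCTGGTAGGATCTTC	CMLNVHIRSGRIF	12
TRBV27-1*01	TRBJ2-6	TGCAGATATCGTGTATCACCCTCCGGGTCATACGTGGCACTGCTGGAATTC	CRYRVSPSGSYVALLEF	16
TRBV29-1*01	TRBJ1-1	TGCTTCATTGCACTTCATCAGTTGCCGCGACGTCGCCCCTTC	CFIALHQLPRRRPF	16
TRBV29-1*01	TRBJ1-4	TGCAGAAGCCTCAGCCAACCAAACGGCTCAGGTATGAAGTTC	CRSLSQPNGSGMKF	13
TRBV29-1*01	TRBJ1-6	TGCAAGACGTTTCGGCTCCTAGGCAAGCGCTTC	CKTFRLLGKRF	10
TRBV29-1*01	TRBJ2-2	TGCCGATCAAGGATGTGGTTTACGCCAGTCGTCGTGTTC	CRSRMWFTPVVVF	8
TRBV30-1*01	TRBJ1-1	TGCGCGCACGATATGTGCTACTCAAAGGATCGGCCTAAATTC	CAHDMCYSKDRPKF	18
TRBV30-1*01	TRBJ1-1	TGCGTGTATCGCAAAAGTGGCCAAGCGGCTGGTTATAGGGAGTGTGTCATATTC	CVYRKSGQAAGYRECVIF	161
TRBV30-1*01	TRBJ1-1	TGCTTGCTTGCCCTAAACGGAAGTGGGCTTGATTCCGACTTC	CLLALNGSGLDSDF	12
TRBV30-1*01	TRBJ1-4	TGCGCCCGCGTGGCCCAGAGAGCCTGCCTTCGTGCGTTC	CARVAQRACLRAF	11
TRBV30-1*01	TRBJ1-5	TGCGCGCTAACCGGACCCGCCCAGGCCGGGTTAGGTGTTACATTC	CALTGPAQAGLGVTF	11
TRBV30-1*01	TRBJ2-5	TGCAAAACGTATGCTAGGCAGCGCACATGGAGTGAATTC	CKTYARQRTWSEF	27
TRBV30-1*01	TRBJ2-5	TGCAATTCATTCAATACCGAGCCTGCACCGAAGAAGCTCCACTTATCCTTC	CNSFNTEPAPKKLHLSF	11
TRBV30-1*01	TRBJ2-5	TGCGCGCTCCGACGCCCAACCTCGGTCTTACAACGTGTTAATGGGTTC	CALRRPTSVLQRVNGF	12
TRBV30-1*01	TRBJ2-7	TGCTCTGCCCCGACAGTGGTGGCCAGGGATGTCCGGGAGCCATTC	CSAPTVVARDVREPF	24
TRBV4-1*01	TRBJ1-2	TGCGTTGAGCGCGTTTGCGGCCGGCGGTTGAGTCCAACGATGACCAGGTTC	CVERVCGRRLSPTMTRF	5
TRBV4-1*01	TRBJ2-1	TGCGCGGAATATATAAGACGTGTATGCATATATTGGGGTTATTATGGTTTCTTC	CAEYIRRVCIYWGYYGFF	15
TRBV4-1*01	TRBJ2-7	TGCTGCTGTGCCGGAATGTCCCTCTGTAGGAGATCGCCAGCTAACGAGCGTATATTC	CCCAGMSLCRRSPANERIF	15
TRBV5-1*01	TRBJ2-2	TGCGGACCCAACATCGGACAGTGTAGGCGGCGGGCTGAACAGTGGTCATTC	CGPNIGQCRRRAEQWSF	7
TRBV5-1*01	TRBJ2-4	TGCCGCGGAAGCGTCCTACGGCCACCAGAGGCATCGACCATGTTC	CRGSVLRPPEASTMF	8
TRBV6-1*01	TRBJ1-4	TGCTGGCCGTATAACGCAGCCACCAAAAGCTTTTATCCTAACAATTTTTTC	CWPYNAATKSFYPNNFF	17
TRBV6-1*01	TRBJ2-4	TGCCTAGCAGAACCTCCCATGTGCCGGAAACTTAAGGTTGCCGCGACTCATGAGTTCTTC	CLAEPPMCRKLKVAATHEFF	10
TRBV6-1*01	TRBJ2-6	TGCCAAATTATAGACTGCGGGTTTTTCTGCAAGTTC	CQIIDCGFFCKF	18
TRBV6-1*01	TRBJ2-7	TGCTTACAGAATGAAGCGCCGACGCCGTTTGTAATCGTCTGGGACTTC	CLQNEAPTPFVIVWDF	4
TRBV7-1*01	TRBJ1-6	TGCAGTTCACGGCTGGAGCGACTCGAACACTCTATTGAAATCTTC	CSSRLERLEHSIEIF	9
TRBV7-1*01	TRBJ2-4	TGCAAGGAGACAGCCGATAGTCAGCACTTTTTGGAAGGAACAGCGTTC	CKETADSQHFLEGTAF	13
TRBV7-1*01	TRBJ2-5	TGCATGCCGCTGGGGGTAGAACATAGCTTAACTCGTTTAGACTCCCCATTC	CMPLGVEHSLTRLDSPF	8
TRBV7-1*01	TRBJ2-5	TGCCTAAACCTCCAAGATTGCGCTACACCCCTAGACTTC	CLNLQDCATPLDF	11
TRBV9-1*01	TRBJ1-1	TGCATGAATCCTCATCGCGACTGCCCGCGTTTTGACTTC	CMNPHRDCPRFDF	10
TRBV9-1*01	TRBJ1-3	TGCCTGGATGAGCGTGATGGACCCAACATTGGAGTTGAAGCTTCTTTC	CLDERDGPNIGVEASF	12
TRBV9-1*01	TRBJ2-5	TGCTGCTTACATTGTATCGGTTCTCCTTTCTCCGGAACCCGTATCCAGGGTTTC	CCLHCIGSPFSGTRIQGF	9
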