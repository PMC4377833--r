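name: colorectal5
loci:
  BAT25:
    chromosome: 4q12
    coordinates: 55598151-55598274
    repeat_class: mononucleotide
    forward_primer: TCGCCTCCAAGAATGTAAGT
    reverse_primer: TCTGCATTTTAACTATGGCTC
    amplicon_length: 123
    modal_length: 123
  BAT26:
    chromosome: 2p
    coordinates: 47641487-47641608
    repeat_class: mononucleotide
    forward_primer: TGACTACTTTTGACTTCAGCC
    reverse_primer: AACCATTCAACATTTTTAACCC
    amplicon_length: 121
    modal_length: 121
  BAT34c4:
    chromosome: 17p13.1
    coordinates: 7572124-7572254
    repeat_class: mononucleotide
    forward_primer: ACCCTGGAGGATTTCATCTC
    reverse_primer: AACAAAGCGAGACCCAGTCT
    amplicon_length: 130
    modal_length: 130
  D18S55:
    chromosome: 18q22.1
    coordinates: 61873501-61873648
    repeat_class: dinucleotide
    forward_primer: GGGAAGTCAAATGCAAATC
    reverse_primer: AGCTTCTGAGTAATCTTATGCTGTG
    amplicon_length: 147
    modal_length: 147
  D5S346:
    chromosome: 5q22.2
    coordinates: 112213624-112213748
    repeat_class: dinucleotide
    forward_primer: ACTCACTCTAGTGATAAATCGGG
    reverse_primer: AGCAGATAAGACAGTATTACTAGTT
    amplicon_length: 124
    modal_length: 124
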