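0.00000000 0.00000000 0.00000000 0.79931091 0.72583451 0.12499692 0.49094462 0.31969971 0.34620937 0.98344893 0.09779939 0.23792865 0.11747596 0.65651863 0.86645661 0.63013074 0.39525880 0.07907157 0.32580172 0.36808857 0.93851133 0.60905814 0.54399148 0.42585148 0.82459290 0.01471657 0.67647323 0.88973999
0.00000000 0.00000000 0.00000000 -0.16048084 0.33176107 -0.63601737 0.74463878 -0.93834311 -0.74698179 0.09216013 0.90718407 -0.31263887 0.65826284 -0.73268730 -0.46450781 0.67482562 0.91850518 0.15362732 0.23924506 0.53254857 -0.23028710 0.09716233 -0.67624812 -0.24684898 0.55842073 -0.96362549 -0.37256619 0.24955995
0.00000000 0.00000000 0.00000000 0.57909236 0.60257685 0.76148387 0.45220180 0.13154584 -0.56758900 0.15599587 -0.40920942 -0.91959061 0.74356535 -0.17931150 0.18299029 -0.38411670 -0.01089595 -0.98496007 0.91466663 -0.76216981 -0.25722431 -0.78715161 0.49675118 0.87046889 0.09062471 -0.26685079 -0.63527821 -0.38220750
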