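# Synthetic stand-in for a published Top-30 mtDNA deletion junction catalog.
# Only the canonical common deletion (8471-13449) and the three junctions
# with breakpoint-proximal SNPs are literature junctions; the remaining
# entries are synthetic placeholders. Supply the published catalog for
# analyses of real data.
bp5	bp3
8471	13449
7816	14807
12369	14004
8775	14771
689	2303
778	3005
867	3707
956	4409
1045	5111
1134	5813
1223	6515
1312	7217
1401	7919
1490	8621
1579	9323
1668	10025
1757	10727
1846	3429
1935	4131
2024	4833
2113	5535
2202	6237
2291	6939
2380	7641
2469	8343
2558	9045
2647	9747
2736	10449
2825	11151
2914	11853
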