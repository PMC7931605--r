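chrom,bins_wap,bins_map,cm_wap,cm_map
Chr1,85,86,93.86,74.92
Chr2,74,70,70.57,73.14
Chr3,90,98,63.03,78.66
Chr4,94,109,97.01,68.04
Chr5,64,79,85.78,67.94
Chr6,90,108,88.61,84.08
Chr7,79,64,88.95,66.44
Chr8,91,92,70.30,78.61
Chr9,65,74,67.02,61.25
Chr10,62,73,49.89,62.42
Chr11,99,96,73.76,78.73
Chr12,61,78,55.65,80.26
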