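rank,terms,delta_aicc,df,waicc_printed,pct_de
1,CURE.PC1 + CURE.PC2 + HDT + HDP + TOPO.PC1 + RIVERS + VEGE.PC2,0,96,0.95,80.3
2,CURE.PC1 + CURE.PC2 + HDT + HDP + TOPO.PC1 + RIVERS + VEGE.PC1 + VEGE.PC2,6.49,102,0.03,80.2
3,CURE.PC1 + CURE.PC2 + HDT + HDP + TOPO.PC1 + TOPO.PC2 + RIVERS + VEGE.PC2,9.41,102,0.009,79.9
4,FULL MODEL,14.06,108,0.001,81
5,CURE.PC1 + CURE.PC2 + HDT + HDP + TOPO.PC1 + RIVERS + VEGE.PC1 + VEGE.PC2 (alt),25.72,96,<0.001,79.8
6,CURE.PC1 + CURE.PC2 + HDT + TOPO.PC1 + RIVERS + VEGE.PC2,32.36,90,<0.001,77.7
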