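{"chromosomeLoss":0.0005531,"geneConversion":3e-06,"complex":5.4e-06}
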