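{"name":"chrII-centromeric-URA3","chromLengthKb":813,"centromereKb":238,"loci":[{"name":"TRP1","kb":5,"channel":"trp","alleleA":"TRP1-2","alleleB":"TRP1-1","functionalA":true,"functionalB":false,"_row":"TRP1"},{"name":"HYG","kb":230,"channel":"hyg","alleleA":"HYG-2","alleleB":"HYG-1","functionalA":true,"functionalB":false,"_row":"HYG"},{"name":"URA3","kb":241,"channel":"foa","alleleA":"URA3-2","alleleB":"ura3-1","functionalA":true,"functionalB":false,"_row":"URA3"},{"name":"TYR1","kb":583,"channel":"none","alleleA":"TYR1-2","alleleB":"TYR1-1","functionalA":false,"functionalB":false,"_row":"TYR1"},{"name":"NAT","kb":795,"channel":"nat","alleleA":"NAT-2","alleleB":"NAT-1","functionalA":true,"functionalB":false,"_row":"NAT"}]}
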