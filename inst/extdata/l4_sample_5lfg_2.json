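{"L":4,"lfgs":["0001","0011","0100","1001","1110"]}
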