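{"L":4,"lfgs":["0001","0101","0110","1010","1101"]}
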