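category,count
first_order,5
shape,1
texture,8
wavelet,132
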