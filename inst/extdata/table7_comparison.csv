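scheme,X1,X2,X3,X4,X5,Y_2,Y_8,Y_24
original,40.000,10.000,5.000,15.000,12.800,20.900,59.500,91.500
45,38.422,13.513,6.275,17.068,7.523,22.747,64.983,100.227
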