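##TITLE=synthetic demonstration spectrum (not measured data)
##JCAMP-DX=4.24
##DATA TYPE=INFRARED SPECTRUM
##XUNITS=1/CM
##YUNITS=ABSORBANCE
##NPOINTS=12
##FIRSTX=1000
##LASTX=1022
##DELTAX=2
##XYDATA=(X++(Y..Y))
1000 0.112 0.135 0.171 0.198
1008 0.176 0.141 0.118 0.104
1016 0.097 0.095 0.094 0.094
##END=
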