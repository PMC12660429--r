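sex,age,L,M,S
F,13,-1.3,19.2,0.105
F,13.5,-1.29,19.46,0.1045
F,14,-1.28,19.72,0.104
F,14.5,-1.27,19.98,0.1035
F,15,-1.26,20.24,0.103
F,15.5,-1.25,20.5,0.1025
F,16,-1.24,20.76,0.102
F,16.5,-1.23,21.02,0.1015
F,17,-1.22,21.28,0.101
F,17.5,-1.21,21.54,0.1005
F,18,-1.2,21.8,0.1
M,13,-1.4,18.9,0.1
M,13.5,-1.39,19.21,0.0995
M,14,-1.38,19.52,0.099
M,14.5,-1.37,19.83,0.0985
M,15,-1.36,20.14,0.098
M,15.5,-1.35,20.45,0.0975
M,16,-1.34,20.76,0.097
M,16.5,-1.33,21.07,0.0965
M,17,-1.32,21.38,0.096
M,17.5,-1.31,21.69,0.0955
M,18,-1.3,22,0.095
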