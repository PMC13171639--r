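"sex","age","L","M","S"
"female",5,-1.6,15.3,0.09
"female",6,-1.58,15.78,0.092
"female",7,-1.56,16.26,0.094
"female",8,-1.54,16.74,0.096
"female",9,-1.52,17.22,0.098
"female",10,-1.5,17.7,0.1
"female",11,-1.48,18.18,0.102
"female",12,-1.46,18.66,0.104
"female",13,-1.44,19.14,0.106
"female",14,-1.42,19.62,0.108
"female",15,-1.4,20.1,0.11
"female",16,-1.38,20.58,0.112
"female",17,-1.36,21.06,0.114
"female",18,-1.34,21.54,0.116
"female",19,-1.32,22.02,0.118
"male",5,-1.6,15.2,0.09
"male",6,-1.58,15.68,0.092
"male",7,-1.56,16.16,0.094
"male",8,-1.54,16.64,0.096
"male",9,-1.52,17.12,0.098
"male",10,-1.5,17.6,0.1
"male",11,-1.48,18.08,0.102
"male",12,-1.46,18.56,0.104
"male",13,-1.44,19.04,0.106
"male",14,-1.42,19.52,0.108
"male",15,-1.4,20,0.11
"male",16,-1.38,20.48,0.112
"male",17,-1.36,20.96,0.114
"male",18,-1.34,21.44,0.116
"male",19,-1.32,21.92,0.118
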