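"review_id","trial_id","quality_score","n_patients"
"rev001","rev001_ab_01",3.5,212
"rev001","rev001_ab_02",4,167
"rev001","rev001_ac_01",4,140
"rev001","rev001_ac_02",3,188
"rev001","rev001_bc_01",4,128
"rev001","rev001_bc_02",4,221
"rev002","rev002_ab_01",2.5,110
"rev002","rev002_ab_02",3,169
"rev002","rev002_ac_01",4,163
"rev002","rev002_ac_02",3.5,162
"rev002","rev002_bc_01",4.5,122
"rev002","rev002_bc_02",3.5,130
"rev003","rev003_ab_01",4,132
"rev003","rev003_ab_02",4,227
"rev003","rev003_ac_01",4.5,173
"rev003","rev003_ac_02",4,157
"rev003","rev003_bc_01",3.5,177
"rev003","rev003_bc_02",4,117
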