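"review_id","trial_id","comparison","treatment","events","total"
"rev001","rev001_ab_01","AvB","B",20,101
"rev001","rev001_ab_01","AvB","A",39,111
"rev001","rev001_ab_02","AvB","B",58,102
"rev001","rev001_ab_02","AvB","A",44,65
"rev001","rev001_ac_01","AvC","C",37,54
"rev001","rev001_ac_01","AvC","A",49,86
"rev001","rev001_ac_02","AvC","C",83,115
"rev001","rev001_ac_02","AvC","A",52,73
"rev001","rev001_bc_01","BvC","B",16,46
"rev001","rev001_bc_01","BvC","C",43,82
"rev001","rev001_bc_02","BvC","B",22,101
"rev001","rev001_bc_02","BvC","C",46,120
"rev002","rev002_ab_01","AvB","B",23,58
"rev002","rev002_ab_01","AvB","A",28,52
"rev002","rev002_ab_02","AvB","B",29,75
"rev002","rev002_ab_02","AvB","A",44,94
"rev002","rev002_ac_01","AvC","C",46,72
"rev002","rev002_ac_01","AvC","A",69,91
"rev002","rev002_ac_02","AvC","C",59,75
"rev002","rev002_ac_02","AvC","A",68,87
"rev002","rev002_bc_01","BvC","B",2,50
"rev002","rev002_bc_01","BvC","C",0,72
"rev002","rev002_bc_02","BvC","B",40,50
"rev002","rev002_bc_02","BvC","C",73,80
"rev003","rev003_ab_01","AvB","B",8,87
"rev003","rev003_ab_01","AvB","A",8,45
"rev003","rev003_ab_02","AvB","B",43,112
"rev003","rev003_ab_02","AvB","A",37,115
"rev003","rev003_ac_01","AvC","C",30,71
"rev003","rev003_ac_01","AvC","A",39,102
"rev003","rev003_ac_02","AvC","C",56,88
"rev003","rev003_ac_02","AvC","A",43,69
"rev003","rev003_bc_01","BvC","B",90,117
"rev003","rev003_bc_01","BvC","C",43,60
"rev003","rev003_bc_02","BvC","B",28,47
"rev003","rev003_bc_02","BvC","C",53,70
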