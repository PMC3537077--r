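"review_id","assessor_id","instrument","item","score"
"rev001","A1","TSA","participants",4.5
"rev001","A1","ECA","participants",3.5
"rev001","A1","TSA","interventions",4
"rev001","A1","ECA","interventions",4
"rev001","A1","TSA","outcomes",3.5
"rev001","A1","ECA","outcomes",3.5
"rev001","A2","TSA","participants",3.75
"rev001","A2","ECA","participants",4
"rev001","A2","TSA","interventions",4.25
"rev001","A2","ECA","interventions",4.5
"rev001","A2","TSA","outcomes",3.5
"rev001","A2","ECA","outcomes",4
"rev002","A1","TSA","participants",4.25
"rev002","A1","ECA","participants",5
"rev002","A1","TSA","interventions",4.75
"rev002","A1","ECA","interventions",4.5
"rev002","A1","TSA","outcomes",3.75
"rev002","A1","ECA","outcomes",4
"rev002","A2","TSA","participants",3.5
"rev002","A2","ECA","participants",3.5
"rev002","A2","TSA","interventions",4
"rev002","A2","ECA","interventions",4
"rev002","A2","TSA","outcomes",4.75
"rev002","A2","ECA","outcomes",3.75
"rev003","A1","TSA","participants",3.25
"rev003","A1","ECA","participants",3
"rev003","A1","TSA","interventions",4
"rev003","A1","ECA","interventions",3.25
"rev003","A1","TSA","outcomes",3.25
"rev003","A1","ECA","outcomes",2.75
"rev003","A2","TSA","participants",3
"rev003","A2","ECA","participants",2.5
"rev003","A2","TSA","interventions",4.25
"rev003","A2","ECA","interventions",3
"rev003","A2","TSA","outcomes",2.25
"rev003","A2","ECA","outcomes",2.75
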