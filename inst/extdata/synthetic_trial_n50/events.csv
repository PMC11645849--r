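"patient_id","event_type","occurrence_index","year_index"
"S00004","IHD",1,1
"S00017","CHF",1,2
"S00021","MI",1,4
"S00025","CHF",1,2
"S00026","STROKE",1,2
"S00031","CHF",1,3
"S00043","MI",1,4
"S00043","STROKE",1,6
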