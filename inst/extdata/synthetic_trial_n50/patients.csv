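"patient_id","age","female","diabetes_duration","prior_IHD","prior_MI","prior_STROKE","prior_CHF","prior_BLINDNESS","prior_AMPUTATION","prior_RENAL_FAILURE","prior_ULCER","death_time","censor_time","administrative_end_time"
"S00001",47.7,0,24,TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,5.2453499098774,5.2453499098774
"S00002",71.4,0,17.6,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,3.23490496561863,3.23490496561863
"S00003",47,1,12.2,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,4.15786252531689,4.15786252531689
"S00004",65.8,0,8,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.53059880586807,4.53059880586807
"S00005",56,0,60.4,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,3.75583799788728,3.75583799788728
"S00006",53.7,1,8.1,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,0.764152847812511,0.764152847812511
"S00007",61.9,0,25.5,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,4.96920670603868,4.96920670603868
"S00008",58.4,0,6.9,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.72089301538654,4.72089301538654
"S00009",65.4,0,11.2,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,NA,5.99563052656595,5.99563052656595
"S00010",62.1,0,11.1,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.22850073815789,1.22850073815789
"S00011",71.2,0,5.2,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,5.05677591613494,5.05677591613494
"S00012",73.9,1,9,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,2.71112310921308,2.71112310921308
"S00013",52.1,0,13.2,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.24365724308882,4.24365724308882
"S00014",59.8,0,29.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.21481027640402,1.21481027640402
"S00015",86,0,29.8,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.64568560698535,4.64568560698535
"S00016",42.7,0,9.3,TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,1.35975686716847,1.35975686716847
"S00017",66.8,1,4.5,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,NA,2.28534664725885,2.28534664725885
"S00018",71.1,0,18.4,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,2.5,5.34893975488376,5.34893975488376
"S00019",61.9,0,16.2,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,3.38221727020573,3.38221727020573
"S00020",60.6,0,11.9,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,5.67184454633389,5.67184454633389
"S00021",55.2,1,13.5,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,5.16853375965729,5.16853375965729
"S00022",61.7,0,21.8,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.99546956073027,1.99546956073027
"S00023",57.6,1,7.7,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.84792541549541,1.84792541549541
"S00024",59.8,1,20.2,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.09608497004956,1.09608497004956
"S00025",55.1,0,24.1,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.83828130189795,1.83828130189795
"S00026",63.1,0,14.2,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,1.5,4.70627149834763,4.70627149834763
"S00027",61.4,0,16.6,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,0.90457017836161,0.90457017836161
"S00028",63.5,0,20.7,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,2.39656795898918,2.39656795898918
"S00029",49.5,1,7.8,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.12082277467858,2.34188535960857
"S00030",66.7,1,15,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.66996814252343,1.66996814252343
"S00031",74.8,0,5.9,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,3.11196920869406,3.11196920869406
"S00032",65,1,9.1,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.93081395735499,1.93081395735499
"S00033",72.7,1,7.5,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,0.5,3.08228236425202,3.08228236425202
"S00034",49.3,1,21.3,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,5.06510390061885,5.06510390061885
"S00035",63.2,0,29,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.92839658297936,4.9424575525336
"S00036",49.5,1,8.3,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,0.643060715286992,0.643060715286992
"S00037",62.8,1,5.3,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.1276566243032,4.1276566243032
"S00038",71.9,0,8.7,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.52192573330831,1.52192573330831
"S00039",65.1,0,4.7,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.61992445366923,1.61992445366923
"S00040",71.5,1,10.4,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,1.67142034589779,1.67142034589779
"S00041",55.5,0,11.2,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.29763041995466,4.29763041995466
"S00042",64.1,0,4.4,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,6.72366629703902,6.72366629703902
"S00043",60.8,1,6.6,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,6.4773659252096,6.4773659252096
"S00044",59.8,0,5.5,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.79156291252002,4.79156291252002
"S00045",78,1,16.7,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,4.44362651370466,4.44362651370466
"S00046",62.1,1,18.4,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,1.29764831159264,1.29764831159264
"S00047",55.1,0,4.5,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,NA,3.84552051406354,3.84552051406354
"S00048",66.4,0,8.7,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,3.06646206707228,3.06646206707228
"S00049",64,0,10.7,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,5.78597855672706,5.78597855672706
"S00050",61.7,1,20.4,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,NA,2.97114118700847,2.97114118700847
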