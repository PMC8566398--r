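trial_id,subject,condition,success,time_to_detection_s
fellow1_palpation,1,palpation,FALSE,NA
fellow2_palpation,2,palpation,FALSE,NA
fellow3_palpation,3,palpation,FALSE,NA
fellow4_palpation,4,palpation,TRUE,8
fellow5_palpation,5,palpation,FALSE,NA
fellow1_radioguided,1,radioguided,TRUE,24
fellow2_radioguided,2,radioguided,TRUE,30
fellow3_radioguided,3,radioguided,TRUE,39
fellow4_radioguided,4,radioguided,TRUE,5
fellow5_radioguided,5,radioguided,FALSE,NA
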