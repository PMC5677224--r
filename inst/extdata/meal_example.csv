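user_id,category,label,value,systolic,diastolic,start,end
Bob,Activity,Eating,,,,1000,2800
Bob,Location,Restaurant,,,,1000,2800
Bob,Emotion,Happiness,,,,1005,2795
Bob,Food,FriedFood,,,,1010,2790
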