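review_id,drug_name,text,effectiveness,ease_of_use,satisfaction,age_band,sex,duration
rv1,Methadone,"I use this for diabetic neuopathy. works well with very little side effects.",5,4,5,55-64,male,1 to 2 years
rv2,Elavil,"elavil is an old school antidepressant that is now considered a dirty drug because of its undesired side effects. one of the unintended side effects is to relax the skeletal muscle tissue. I use elavil off label to treat my tmj",4,4,4,45-54,female,6 months to 1 year
rv3,Spironolactone,"I use it for acne. go figure it works",4,5,5,25-34,female,1 to 6 months
rv4,Strattera,"I was prescribed this medication for slight adhd with off label anxiety help.",3,4,3,19-24,unspecified,1 to 6 months
rv5,Viibryd,"It even helps my migraines somewhat (maybe it will be off label in the future for migraine prophylaxis)",4,3,4,35-44,female,1 to 6 months
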