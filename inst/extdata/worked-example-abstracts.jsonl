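{"pmid":"19322566","abstract":"Study detail 1 of the trial protocol was recorded in this sentence. Study detail 2 of the trial protocol was recorded in this sentence. Study detail 3 of the trial protocol was recorded in this sentence. Study detail 4 of the trial protocol was recorded in this sentence. Study detail 5 of the trial protocol was recorded in this sentence. Study detail 6 of the trial protocol was recorded in this sentence. Study detail 7 of the trial protocol was recorded in this sentence. Study detail 8 of the trial protocol was recorded in this sentence. Study detail 9 of the trial protocol was recorded in this sentence. Study detail 10 of the trial protocol was recorded in this sentence. Study detail 11 of the trial protocol was recorded in this sentence. Study detail 12 of the trial protocol was recorded in this sentence. Study detail 13 of the trial protocol was recorded in this sentence. Study detail 14 of the trial protocol was recorded in this sentence. CONCLUSION: A combination of GTI-2040, capecitabine and oxaliplatin is feasible in patients with advanced solid tumors."}
{"pmid":"28101592","abstract":"Study detail 1 of the trial protocol was recorded in this sentence. Study detail 2 of the trial protocol was recorded in this sentence. Study detail 3 of the trial protocol was recorded in this sentence. Study detail 4 of the trial protocol was recorded in this sentence. Study detail 5 of the trial protocol was recorded in this sentence. Study detail 6 of the trial protocol was recorded in this sentence. Study detail 7 of the trial protocol was recorded in this sentence. Study detail 8 of the trial protocol was recorded in this sentence. Study detail 9 of the trial protocol was recorded in this sentence. In conclusion, FCM regimen allows excellent long-lasting response in previously untreated patients with FL."}
{"pmid":"21198717","abstract":"Study detail 1 of the trial protocol was recorded in this sentence. Study detail 2 of the trial protocol was recorded in this sentence. Study detail 3 of the trial protocol was recorded in this sentence. Study detail 4 of the trial protocol was recorded in this sentence. Study detail 5 of the trial protocol was recorded in this sentence. Study detail 6 of the trial protocol was recorded in this sentence. Study detail 7 of the trial protocol was recorded in this sentence. Study detail 8 of the trial protocol was recorded in this sentence. Study detail 9 of the trial protocol was recorded in this sentence. WHAT IS NEW AND CONCLUSION: The use of novel agents such as thalidomide, bortezomib and lenalidomide for RRMM is highly prevalent in France from the first relapse."}
{"pmid":"23197589","abstract":"Study detail 1 of the trial protocol was recorded in this sentence. Study detail 2 of the trial protocol was recorded in this sentence. Study detail 3 of the trial protocol was recorded in this sentence. Study detail 4 of the trial protocol was recorded in this sentence. Study detail 5 of the trial protocol was recorded in this sentence. Study detail 6 of the trial protocol was recorded in this sentence. Study detail 7 of the trial protocol was recorded in this sentence. We conclude that intraventricular rituximab in combination with MTX is feasible and highly active in the treatment of drug-resistant CNS NHL that is refractory or unresponsive to IV rituximab."}
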