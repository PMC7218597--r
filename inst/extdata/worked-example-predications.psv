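#pmid|sentence_id|subject_cui|subject_name|subject_semtypes|predicate|object_cui|object_name|object_semtypes
19322566|19322566.ab.15|C2931852|Advanced Malignant Solid Neoplasm|neop|PROCESS_OF|C0030705|Patients|podg
19322566|19322566.ab.15|C1518922|GTI2040|phsu|TREATS|C0030705|Patients|podg
19322566|19322566.ab.15|C1518922|GTI2040|phsu|TREATS(INFER)|C2931852|Advanced Malignant Solid Neoplasm|neop
19322566|19322566.ab.15|C0671970|capecitabine|phsu,orch|TREATS|C0030705|Patients|podg
19322566|19322566.ab.15|C0671970|capecitabine|phsu,orch|TREATS(INFER)|C2931852|Advanced Malignant Solid Neoplasm|neop
19322566|19322566.ab.15|C0069717|oxaliplatin|phsu,orch|TREATS|C0030705|Patients|podg
19322566|19322566.ab.15|C0069717|oxaliplatin|phsu,orch|TREATS(INFER)|C2931852|Advanced Malignant Solid Neoplasm|neop
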