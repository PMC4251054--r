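pattern,replacement,label
"(?i)://(www\.)?webcitation([/?]|$)","://\1webcitation.org\2",webcitation missing .org suffix
"(?i)://(www\.)?clinical-trials\.gov","://\1clinicaltrials.gov",hyphenated clinical-trials
"(?i)://(www\.)?clinicaltrails\.gov","://\1clinicaltrials.gov",trials misspelled as trails
"(?i)://clinicaltrials([/?]|$)","://clinicaltrials.gov\1",clinicaltrials missing top-level domain
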