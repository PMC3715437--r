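# Example exclusion list for the manual-curation step of
# filter_offpathway(): small GTPases of the ARF/SAR and RAB families,
# which occur in all three routes and bind promiscuously.
P84077
P61204
P18085
P84085
Q9NR31
Q9Y6B6
P62820
P61006
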