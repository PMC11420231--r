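sample_id	individual_id
Panoria 1	PAN-008
Panoria 2	PAN-009
Panoria 3	PAN-033
Panoria 4	PAN-034
Panoria 5	PAN-042
Panoria 6	PAN-043
Panoria 7	PAN-044
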