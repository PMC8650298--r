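name	rs_id	associated_region
C-14010	rs145946881	East African
T-13910	rs4988235	European
A-22018	rs182549	European (LD with T-13910)
G-13907	rs41525747	East African
T-13915	rs41380347	Arabian
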