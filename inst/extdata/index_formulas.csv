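name,formula
evans_ratio,E/A
bicaudate_ratio,F/A
huckman_number,E+F
huckman_ratio,(E+F)/A
third_ventricular_ratio,H/A
ventricle_index,J/F
temporal_horn_ratio,O/A
suprasellar_cistern_ratio,P/A
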