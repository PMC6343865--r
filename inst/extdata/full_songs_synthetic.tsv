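song_id	sequence
fs01	15-12-4b
fs02	17-13b-12-4b
fs03	15-14a-12-4b
fs04	15-14a-13b-12-4b
fs05	17-14a-13b-12-4b
fs06	17-15-14a-13b-12-4b
fs07	15-13c-14a-13b-12-4b
fs08	14a-13b-12-4b-8
fs09	11b-14a-13b-12-4b-6
fs10	13c-14a-14b-13b-12-4b-8
fs11	15-11b-13c-14a-13b-12-4b-8
fs12	11b-13c-14a-14b-3c-13a-13b-12-4b
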