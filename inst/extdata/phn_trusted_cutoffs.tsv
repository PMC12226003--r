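# Synthetic default per-family trusted cutoffs (bit score) used by the
# simulator and tests. Real screens must supply the trusted cutoffs of
# their own curated HMM models.
family	trusted_cutoff
phnC	60
phnD	55
phnE	50
phnF	45
phnG	40
phnH	42
phnI	65
phnJ	70
phnK	62
phnL	48
phnM	58
phnN	44
phnO	41
phnP	52
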