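# Illustrative drug -> indication-confounding category map (synthetic
# example assembled from public drug labels; NOT a licensed terminology
# extract). Categories: autoimmune, reproductive_tract_infection, metabolic,
# thyroid, progestogen_use.
ADALIMUMAB: [autoimmune]
INFLIXIMAB: [autoimmune]
CERTOLIZUMAB PEGOL: [autoimmune]
ETANERCEPT: [autoimmune]
NATALIZUMAB: [autoimmune]
VEDOLIZUMAB: [autoimmune]
FINGOLIMOD: [autoimmune]
INTERFERON BETA-1A: [autoimmune]
RISANKIZUMAB: [autoimmune]
LEVONORGESTREL: [progestogen_use]
ETONOGESTREL: [progestogen_use]
MEDROXYPROGESTERONE: [progestogen_use]
PROGESTERONE: [progestogen_use]
ULIPRISTAL: [progestogen_use]
METRONIDAZOLE: [reproductive_tract_infection]
AZITHROMYCIN: [reproductive_tract_infection]
METFORMIN: [metabolic]
INSULIN: [metabolic]
LEVOTHYROXINE: [thyroid]
METHIMAZOLE: [thyroid]
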