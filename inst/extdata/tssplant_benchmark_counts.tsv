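# Reference benchmark of gene-anchored TSS prediction on 2-kb sequences
# upstream of the CDS of 100 randomly selected genes per species.
# Counts (predictions, true positives, positives) and the reported
# sensitivity/precision/F percentages for the Promoter-Index method and for
# TSSPlant run without selection and with max-score selection.
species	method	n_pred	tp	n_pos	sensitivity	precision	f
arabidopsis	promoter_index	94	67	100	67.00	71.28	69.07
arabidopsis	tssplant_no_selection	402	69	100	69.00	17.16	27.49
arabidopsis	tssplant_max_score	100	36	100	36.00	36.00	36.00
rice	promoter_index	61	33	100	33.00	54.10	40.99
rice	tssplant_no_selection	416	56	100	56.00	13.46	21.71
rice	tssplant_max_score	100	15	100	15.00	15.00	15.00
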