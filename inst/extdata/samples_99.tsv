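sample_id	donor_id	region
d1_FL	d1	FL
d2_FL	d2	FL
d3_FL	d3	FL
d4_FL	d4	FL
d5_FL	d5	FL
d6_FL	d6	FL
d7_FL	d7	FL
d8_FL	d8	FL
d1_TL	d1	TL
d2_TL	d2	TL
d3_TL	d3	TL
d4_TL	d4	TL
d5_TL	d5	TL
d6_TL	d6	TL
d7_TL	d7	TL
d8_TL	d8	TL
d1_PL	d1	PL
d2_PL	d2	PL
d3_PL	d3	PL
d4_PL	d4	PL
d5_PL	d5	PL
d7_PL	d7	PL
d8_PL	d8	PL
d1_OL	d1	OL
d2_OL	d2	OL
d3_OL	d3	OL
d4_OL	d4	OL
d5_OL	d5	OL
d6_OL	d6	OL
d7_OL	d7	OL
d8_OL	d8	OL
d2_CB	d2	CB
d3_CB	d3	CB
d4_CB	d4	CB
d5_CB	d5	CB
d6_CB	d6	CB
d7_CB	d7	CB
d8_CB	d8	CB
d1_BS	d1	BS
d2_BS	d2	BS
d3_BS	d3	BS
d5_BS	d5	BS
d6_BS	d6	BS
d7_BS	d7	BS
d1_THA_HT	d1	THA/HT
d2_THA_HT	d2	THA/HT
d3_THA_HT	d3	THA/HT
d4_THA_HT	d4	THA/HT
d5_THA_HT	d5	THA/HT
d6_THA_HT	d6	THA/HT
d7_THA_HT	d7	THA/HT
d8_THA_HT	d8	THA/HT
d1_OC	d1	OC
d2_OC	d2	OC
d3_OC	d3	OC
d4_OC	d4	OC
d5_OC	d5	OC
d6_OC	d6	OC
d7_OC	d7	OC
d8_OC	d8	OC
d1_CC	d1	CC
d2_CC	d2	CC
d3_CC	d3	CC
d4_CC	d4	CC
d5_CC	d5	CC
d6_CC	d6	CC
d7_CC	d7	CC
d8_CC	d8	CC
d1_VT	d1	VT
d2_VT	d2	VT
d3_VT	d3	VT
d4_VT	d4	VT
d5_VT	d5	VT
d6_VT	d6	VT
d7_VT	d7	VT
d8_VT	d8	VT
d1_HIP	d1	HIP
d2_HIP	d2	HIP
d3_HIP	d3	HIP
d4_HIP	d4	HIP
d5_HIP	d5	HIP
d6_HIP	d6	HIP
d7_HIP	d7	HIP
d8_HIP	d8	HIP
d1_AN	d1	AN
d2_AN	d2	AN
d3_AN	d3	AN
d4_AN	d4	AN
d5_AN	d5	AN
d6_AN	d6	AN
d7_AN	d7	AN
d8_AN	d8	AN
d1_OB_OT	d1	OB/OT
d2_OB_OT	d2	OB/OT
d4_OB_OT	d4	OB/OT
d5_OB_OT	d5	OB/OT
d6_OB_OT	d6	OB/OT
d7_OB_OT	d7	OB/OT
d8_OB_OT	d8	OB/OT
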