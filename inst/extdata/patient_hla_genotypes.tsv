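patient_id	locus	allele1	allele2
MS-1	A	A*02:01	A*02:01
MS-1	B	B*15:01	B*44:02
MS-1	DRB1	DRB1*13:02	DRB1*15:01
MS-1	DQ	DQA1*01:02-DQB1*06:02	DQA1*01:02-DQB1*06:04
MS-1	DP	DPA1*01:03/05-DPB1*04:01	DPA1*01:03/05-DPB1*04:01
MS-2	A	A*02:01	A*02:01
MS-2	B	B*07:02	B*27:05
MS-2	DRB1	DRB1*01:01	DRB1*15:01
MS-2	DQ	DQA1*01:01-DQB1*05:01	DQA1*01:02-DQB1*06:02
MS-2	DP	DPA1*01:03-DPB1*04:01	DPA1*01:03-DPB1*04:02
MS-3	A	A*03:01	A*25:01
MS-3	B	B*07:02	B*18:01
MS-3	DRB1	DRB1*15:01	DRB1*15:01
MS-3	DQ	DQA1*01:02-DQB1*06:02	DQA1*01:02-DQB1*06:02
MS-3	DP	DPA1*01:03/05-DPB1*04:01	DPA1*01:03/05-DPB1*04:01
MS-4	A	A*03:01	A*24:02
MS-4	B	B*07:02	B*35:01
MS-4	DRB1	DRB1*01:01	DRB1*15:01
MS-4	DQ	DQA1*01:01-DQB1*05:01	DQA1*01:02-DQB1*06:02
MS-4	DP	DPA1*01:03-DPB1*02:01	DPA1*01:03-DPB1*20:01
MS-5	A	A*02:01	A*30:01
MS-5	B	B*13:02	B*44:03
MS-5	DRB1	DRB1*07:01	DRB1*15:01
MS-5	DQ	DQA1*01:02-DQB1*06:02	DQA1*02:01-DQB1*02:02
MS-5	DP	DPA1*01:03/05-DPB1*04:01	DPA1*01:03/05-DPB1*04:01
MS-6	A	A*03:01	A*32:01
MS-6	B	B*07:02	B*08:01
MS-6	DRB1	DRB1*03:01	DRB1*13:01
MS-6	DQ	DQA1*01:03-DQB1*06:03	DQA1*05:01-DQB1*02:01
MS-6	DP	DPA1*01:03-DPB1*01:01	DPA1*02:01-DPB1*04:01
MS-7	A	A*24:02	A*69:01
MS-7	B	B*35:01	B*44:02
MS-7	DRB1	DRB1*11:04	DRB1*15:01
MS-7	DQ	DQA1*01:02-DQB1*06:02	DQA1*05:05-DQB1*03:01
MS-7	DP	DPA1*01:03-DPB1*04:01	DPA1*01:03-DPB1*04:02
MS-8	A	A*01:01	A*31:01
MS-8	B	B*07:02	B*15:01
MS-8	DRB1	DRB1*15:01	DRB1*15:01
MS-8	DQ	DQA1*01:02-DQB1*06:02	DQA1*01:02-DQB1*06:02
MS-8	DP	DPA1*01:03-DPB1*02:01	DPA1*01:03-DPB1*02:01
MS-9	A	A*25:01	A*31:01
MS-9	B	B*18:01	B*44:03
MS-9	DRB1	DRB1*07:01	DRB1*08:01
MS-9	DQ	DQA1*02:01-DQB1*02:02	DQA1*04:01-DQB1*04:02
MS-9	DP	DPA1*01:03-DPB1*02:01	DPA1*01:03-DPB1*04:01
MS-10	A	A*03:01	A*29:02
MS-10	B	B*35:01	B*45:01
MS-10	DRB1	DRB1*01:01	DRB1*04:05
MS-10	DQ	DQA1*01:01-DQB1*05:01	DQA1*03:03-DQB1*03:02
MS-10	DP	DPA1*01:03-DPB1*04:01	DPA1*01:03-DPB1*04:02
MS-11	A	A*02:01	A*02:01
MS-11	B	B*15:01	B*40:01
MS-11	DRB1	DRB1*04:04	DRB1*11:01
MS-11	DQ	DQA1*03:01-DQB1*03:01	DQA1*05:05-DQB1*03:02
MS-11	DP	DPA1*01:03-DPB1*02:01	DPA1*02:02-DPB1*05:01
OIND-1	A	A*01:01	A*68:01
OIND-1	B	B*08:01	B*35:03
OIND-1	DRB1	DRB1*03:01	DRB1*15:01
OIND-1	DQ	DQA1*01:02-DQB1*06:02	DQA1*05:01-DQB1*02:01
OIND-1	DP	DPA1*02:01/02/03:02-DPB1*01:01	DPA1*01:03-DPB1*03:01
OIND-2	A	A*01:01	A*02:05
OIND-2	B	B*08:01	B*50:01
OIND-2	DRB1	DRB1*03:01	DRB1*07:01
OIND-2	DQ	DQA1*02:01-DQB1*02:02	DQA1*05:01-DQB1*02:01
OIND-2	DP	DPA1*01:03-DPB1*04:02	DPA1*01:03-DPB1*104:01
OIND-3	A	A*01:01	A*01:01
OIND-3	B	B*08:01	B*08:01
OIND-3	DRB1	DRB1*03:01	DRB1*03:01
OIND-3	DQ	DQA1*05:01-DQB1*02:01	DQA1*05:01-DQB1*02:01
OIND-3	DP	DPA1*02:01-DPB1*01:01	DPA1*02:01-DPB1*14:01
OIND-4	A	A*02:01	A*02:01
OIND-4	B	B*15:01	B*27:05
OIND-4	DRB1	DRB1*01:01	DRB1*04:01
OIND-4	DQ	DQA1*01:01-DQB1*05:01	DQA1*03:01-DQB1*03:02
OIND-4	DP	DPA1*01:03-DPB1*04:01	DPA1*01:03-DPB1*04:02
OIND-5	A	A*03:01	A*68:01
OIND-5	B	B*07:02	B*44:02
OIND-5	DRB1	DRB1*07:01	DRB1*15:01
OIND-5	DQ	DQA1*01:02-DQB1*06:02	DQA1*02:01-DQB1*02:02
OIND-5	DP	DPA1*01:03/03:01/04:01-DPB1*04:02	DPA1*02:01-DPB1*11:01
OIND-6	A	A*01:01	A*01:01
OIND-6	B	B*08:01	B*08:01
OIND-6	DRB1	DRB1*03:01	DRB1*03:01
OIND-6	DQ	DQA1*05:01-DQB1*02:01	DQA1*05:01-DQB1*02:01
OIND-6	DP	DPA1*02:01/02/03:02-DPB1*01:01	DPA1*1:03/03:01/04:01-DPB1*04:02
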