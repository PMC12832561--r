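variable	category	n
gender	male	1354
gender	female	1221
gender	missing	387
age	<18	6
age	18-64	395
age	>=65	1034
age	missing	1527
route	oral	2650
route	topical	228
route	other	84
weight	<50 kg	90
weight	50-100 kg	633
weight	>100 kg	77
weight	missing	2162
reporter	healthcare_professional	896
reporter	consumer	1062
reporter	other	686
reporter	missing	318
indication	chronic obstructive pulmonary disease	1390
indication	missing	1279
indication	psoriasis	86
indication	synthetic filler indication	207
country	united states	2275
country	germany	450
country	canada	32
country	south korea	25
country	netherlands	16
country	synthetic filler country a	15
country	synthetic filler country b	15
country	synthetic filler country c	15
country	synthetic filler country d	15
country	synthetic filler country e	15
country	synthetic filler country f	15
country	synthetic filler country g	15
country	synthetic filler country h	15
country	synthetic filler country i	15
country	synthetic filler country j	15
country	synthetic filler country k	14
year	2013	783
year	2014	305
year	2023	288
year	2012	217
year	2024	214
year	2011	119
year	2015	130
year	2016	130
year	2017	130
year	2018	130
year	2019	130
year	2020	130
year	2021	130
year	2022	126
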