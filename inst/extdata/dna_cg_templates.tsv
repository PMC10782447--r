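residue	atom	element	mass	group	aux
DA	P	P	30.973762	1	FALSE
DA	O1P	O	15.999	1	TRUE
DA	O2P	O	15.999	1	TRUE
DA	O5'	O	15.999	1	FALSE
DA	C5'	C	12.011	2	FALSE
DA	H5'1	H	1.008	2	FALSE
DA	H5'2	H	1.008	2	FALSE
DA	C4'	C	12.011	2	FALSE
DA	H4'	H	1.008	2	FALSE
DA	O4'	O	15.999	2	FALSE
DA	C3'	C	12.011	3	FALSE
DA	H3'	H	1.008	3	FALSE
DA	C2'	C	12.011	3	FALSE
DA	H2'1	H	1.008	3	FALSE
DA	H2'2	H	1.008	3	FALSE
DA	O3'	O	15.999	3	FALSE
DA	C1'	C	12.011	3	FALSE
DA	H1'	H	1.008	3	FALSE
DA	N9	N	14.007	4	FALSE
DA	C8	C	12.011	4	FALSE
DA	H8	H	1.008	4	FALSE
DA	N7	N	14.007	4	FALSE
DA	C5	C	12.011	5	FALSE
DA	C6	C	12.011	5	FALSE
DA	N6	N	14.007	5	FALSE
DA	H61	H	1.008	5	FALSE
DA	H62	H	1.008	5	FALSE
DA	N1	N	14.007	6	FALSE
DA	C2	C	12.011	6	FALSE
DA	H2	H	1.008	6	FALSE
DA	N3	N	14.007	6	FALSE
DA	C4	C	12.011	6	FALSE
DG	P	P	30.973762	1	FALSE
DG	O1P	O	15.999	1	TRUE
DG	O2P	O	15.999	1	TRUE
DG	O5'	O	15.999	1	FALSE
DG	C5'	C	12.011	2	FALSE
DG	H5'1	H	1.008	2	FALSE
DG	H5'2	H	1.008	2	FALSE
DG	C4'	C	12.011	2	FALSE
DG	H4'	H	1.008	2	FALSE
DG	O4'	O	15.999	2	FALSE
DG	C3'	C	12.011	3	FALSE
DG	H3'	H	1.008	3	FALSE
DG	C2'	C	12.011	3	FALSE
DG	H2'1	H	1.008	3	FALSE
DG	H2'2	H	1.008	3	FALSE
DG	O3'	O	15.999	3	FALSE
DG	C1'	C	12.011	3	FALSE
DG	H1'	H	1.008	3	FALSE
DG	N9	N	14.007	4	FALSE
DG	C8	C	12.011	4	FALSE
DG	H8	H	1.008	4	FALSE
DG	N7	N	14.007	4	FALSE
DG	C5	C	12.011	5	FALSE
DG	C6	C	12.011	5	FALSE
DG	O6	O	15.999	5	FALSE
DG	N1	N	14.007	5	FALSE
DG	H1	H	1.008	5	FALSE
DG	C2	C	12.011	6	FALSE
DG	N2	N	14.007	6	FALSE
DG	H21	H	1.008	6	FALSE
DG	H22	H	1.008	6	FALSE
DG	N3	N	14.007	6	FALSE
DG	C4	C	12.011	6	FALSE
DC	P	P	30.973762	1	FALSE
DC	O1P	O	15.999	1	TRUE
DC	O2P	O	15.999	1	TRUE
DC	O5'	O	15.999	1	FALSE
DC	C5'	C	12.011	2	FALSE
DC	H5'1	H	1.008	2	FALSE
DC	H5'2	H	1.008	2	FALSE
DC	C4'	C	12.011	2	FALSE
DC	H4'	H	1.008	2	FALSE
DC	O4'	O	15.999	2	FALSE
DC	C3'	C	12.011	3	FALSE
DC	H3'	H	1.008	3	FALSE
DC	C2'	C	12.011	3	FALSE
DC	H2'1	H	1.008	3	FALSE
DC	H2'2	H	1.008	3	FALSE
DC	O3'	O	15.999	3	FALSE
DC	C1'	C	12.011	3	FALSE
DC	H1'	H	1.008	3	FALSE
DC	N1	N	14.007	4	FALSE
DC	C2	C	12.011	4	FALSE
DC	O2	O	15.999	4	FALSE
DC	N3	N	14.007	5	FALSE
DC	C4	C	12.011	5	FALSE
DC	N4	N	14.007	5	FALSE
DC	H41	H	1.008	5	FALSE
DC	H42	H	1.008	5	FALSE
DC	C5	C	12.011	6	FALSE
DC	H5	H	1.008	6	FALSE
DC	C6	C	12.011	6	FALSE
DC	H6	H	1.008	6	FALSE
DT	P	P	30.973762	1	FALSE
DT	O1P	O	15.999	1	TRUE
DT	O2P	O	15.999	1	TRUE
DT	O5'	O	15.999	1	FALSE
DT	C5'	C	12.011	2	FALSE
DT	H5'1	H	1.008	2	FALSE
DT	H5'2	H	1.008	2	FALSE
DT	C4'	C	12.011	2	FALSE
DT	H4'	H	1.008	2	FALSE
DT	O4'	O	15.999	2	FALSE
DT	C3'	C	12.011	3	FALSE
DT	H3'	H	1.008	3	FALSE
DT	C2'	C	12.011	3	FALSE
DT	H2'1	H	1.008	3	FALSE
DT	H2'2	H	1.008	3	FALSE
DT	O3'	O	15.999	3	FALSE
DT	C1'	C	12.011	3	FALSE
DT	H1'	H	1.008	3	FALSE
DT	N1	N	14.007	4	FALSE
DT	C2	C	12.011	4	FALSE
DT	O2	O	15.999	4	FALSE
DT	N3	N	14.007	5	FALSE
DT	H3	H	1.008	5	FALSE
DT	C4	C	12.011	5	FALSE
DT	O4	O	15.999	5	FALSE
DT	C5	C	12.011	6	FALSE
DT	C7	C	12.011	6	FALSE
DT	H71	H	1.008	6	FALSE
DT	H72	H	1.008	6	FALSE
DT	H73	H	1.008	6	FALSE
DT	C6	C	12.011	6	FALSE
DT	H6	H	1.008	6	FALSE
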