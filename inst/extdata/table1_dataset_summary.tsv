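period	date	clock_time	n_files	n_singers_est	n_ld_sequences	is_total
1	2011-01-27	22:30	4	3	3	0
1	2011-01-30	13:00	6	3	3	0
1	2011-01-31	04:15	4	3	8	0
1	2011-02-02	02:45	4	5	3	0
1		 	18	11	17	1
2	2011-02-05	03:15	4	2	4	0
2	2011-02-07	05:45	4	3	3	0
2	2011-02-09	19:30	4	4	2	0
2	2011-02-10	00:00	4	2	7	0
2		 	16	9	16	1
3	2011-02-18	21:00	6	4	6	0
3	2011-02-20	00:45	4	4	6	0
3	2011-02-24	17:45	4	3	7	0
3	2011-02-25	06:15	4	4	9	0
3		 	18	12	28	1
4	2011-03-02	15:15	4	2	4	0
4	2011-03-08	01:30	4	1	4	0
4	2011-03-11	14:15	4	3	6	0
4	2011-03-12	06:30	4	1	2	0
4		 	18	6	16	1
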