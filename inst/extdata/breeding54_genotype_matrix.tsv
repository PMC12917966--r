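sample	10348	14321	23167	23593	29449	37238	37239	37240	45193	45592	50158	50842	50999	59616	65304	68985	90253	95372	97585	98314	101103	101121	101130	101139	101148	101157	106236	110347	113045	118329	119153	119714
REF	T	G	G	C	T	T	T	T	G	G	T	C	G	C	C	G	A	G	T	G	T	T	T	G	G	T	G	T	T	C	G	C
ALT	A	T	A	A	G	A	A	A	T	T	C	T	A	T	A	T	G	A	G	T	G	G	G	T	T	G	A	G	G	A	T	T
I-22	-	T	-	-	-	A	A	A	T	-	-	-	-	-	-	T	G	-	-	-	-	-	G	T	T	-	-	-	G	A	-	-
I-54	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	G	G	-	-	-	-	-	-	-	T	-
I-56	-	-	A	A	-	-	-	-	T	-	-	T	A	-	-	T	-	-	-	-	G	G	-	T	-	-	-	-	-	N	-	N
I-58	-	-	-	A	-	-	-	-	T	-	-	T	N	-	-	T	-	-	-	-	G	-	-	T	-	-	-	-	-	-	N	-
II-12	-	-	-	N	-	-	-	-	T	-	-	-	-	-	-	T	G	-	-	-	-	-	-	-	-	-	-	N	-	-	N	-
II-16-4	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	-	-	-	-	-	-	-	-	T	T
II-16-5	-	-	A	A	-	A	A	A	T	-	-	T	A	-	-	T	-	-	-	-	G	G	-	-	-	-	-	-	-	-	-	-
II-19	A	-	-	-	-	-	-	-	T	-	-	-	-	T	-	T	-	-	-	-	-	-	-	-	-	G	-	-	-	-	T	-
II-31-5	-	-	-	A	-	A	A	A	T	-	C	T	A	-	-	T	-	-	-	-	G	-	-	T	-	-	A	-	-	-	-	-
II-31-6	-	-	-	-	-	A	A	A	T	-	-	-	-	-	-	T	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
II-4-1	-	-	-	-	-	-	-	-	T	T	-	-	-	-	-	T	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
II-4-5	-	-	-	-	-	-	-	-	T	T	-	-	-	-	-	T	-	-	-	-	-	-	-	-	-	-	-	-	-	N	T	-
II-4-6	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	G	-	-	-	-	-	-	-	-	-	-	-	-	-	T	-
II-51-6	A	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	T	G	-	-	T	-	-	-	-	-	-	N	-
II-55-2	-	-	-	-	N	N	N	N	T	-	-	-	-	-	-	T	G	-	-	-	-	G	-	T	-	-	-	-	-	N	-	-
II-57-2	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	-	-	-	G	-	-	-	-	-	-
II-57-5	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	-	T	T	-	-	-	-	-	-	T
II-6-2	-	T	-	-	-	A	A	A	T	-	-	-	-	-	-	T	-	-	-	-	-	-	G	T	T	-	-	-	G	A	-	-
II-6-6	-	-	A	A	-	-	-	-	T	-	-	T	A	-	-	T	-	-	-	-	G	G	-	T	T	-	-	-	N	-	-	-
III-11	-	-	-	-	-	-	-	-	T	-	-	-	-	-	A	T	-	A	G	-	-	-	-	T	-	-	-	-	-	-	-	-
III-16-1	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	G	G	-	-	-	-	G	-	-	-	-
III-16-4	-	-	N	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	N	G	G	-	-	-	-	G	N	N	-	-
III-16-6	-	-	-	N	-	-	-	-	T	-	-	-	-	-	-	T	G	-	-	-	-	G	G	-	-	-	-	-	-	-	T	-
III-19	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	-	-	-	-	-	-	-	-	T	-
III-20	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	-	-	T	-	-	-	-	-	T	-
III-4-1	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
III-4-4	-	-	-	-	-	-	-	-	T	T	-	-	-	-	-	T	-	-	-	-	-	-	-	-	-	-	-	-	-	N	-	-
III-5	-	-	-	-	N	N	N	N	T	-	-	N	N	-	-	N	G	-	-	-	G	-	-	-	-	-	T	N	-	N	N	N
III-51-3	-	-	-	-	-	-	-	-	T	-	-	-	-	-	A	T	-	A	G	-	-	-	-	T	-	-	-	-	-	-	T	-
III-54-2	-	-	-	A	-	A	A	A	T	-	C	T	A	-	-	T	-	-	-	-	G	-	-	T	-	-	A	-	-	-	-	-
III-55	-	-	-	A	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	G	T	-	-	-	-	-	-	-	-
III-56-1	-	-	-	-	-	N	N	N	T	-	-	-	-	-	-	T	-	-	-	T	G	-	G	-	-	-	-	-	-	-	T	-
III-64	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	-	T	T	-	-	-	-	-	-	-
IV-11-3	N	-	-	A	-	A	A	A	T	-	C	T	A	-	-	T	-	-	-	-	G	-	-	T	-	-	A	-	-	-	-	-
IV-11-5	-	-	-	-	G	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	G	-	-	-	-	-	G	-	N	-
IV-16	-	-	-	A	-	A	A	A	T	-	C	T	A	-	-	T	G	-	-	-	G	-	-	T	-	-	A	-	-	N	-	-
IV-17-1	-	-	-	-	-	-	-	-	N	N	-	-	-	T	-	T	-	-	N	-	-	-	-	-	-	G	-	-	-	N	N	-
IV-17-4	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	-	-	-	-	-	-	-	-	T	-
IV-19	A	-	-	-	-	-	-	-	T	-	-	-	-	T	-	T	-	-	-	-	-	-	-	-	-	G	-	-	-	-	N	A
IV-19-4	-	-	-	-	-	-	-	-	T	-	-	-	-	-	A	T	-	A	G	-	-	-	-	T	-	-	-	-	-	-	-	-
IV-40-2	-	-	-	-	-	-	-	-	T	-	-	T	A	-	-	T	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
IV-40-5	N	-	-	-	-	-	-	-	T	-	-	T	A	-	-	T	-	-	-	-	-	-	G	T	-	-	-	-	-	-	-	-
IV-55	-	-	-	-	G	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	G	-	-	-	-	-	G	-	-	-
IV-57	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	G	G	-	-	-	-	G	-	-	-	-
IV-58-4	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	-	T	-	-	-	-	-	-	-	-
V-1	-	T	-	-	-	A	A	A	T	-	-	-	-	-	-	T	-	-	-	-	-	-	G	T	T	-	-	-	G	A	-	-
V-14	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	-	-	T	-	-	-	-	-	T	-
VI-11	-	-	-	-	-	-	A	A	T	-	-	N	-	-	-	T	-	-	-	T	-	-	-	T	-	G	-	-	-	N	T	-
VI-12	N	-	-	-	-	N	N	N	T	-	-	-	-	-	-	T	-	-	-	-	N	N	N	N	-	-	-	-	-	-	N	N
VI-14	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	-	-	-	-	-	-	-	-	T	T
VI-16	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	G	G	-	-	-	-	G	-	-	-	-
VI-19	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	-	-	-	T	-	G	-	-	-	N	N	N
VI-58	-	-	-	-	-	-	-	-	T	-	-	-	-	-	-	T	-	-	-	T	G	-	-	T	-	-	-	-	-	N	T	-
VI-58-6	-	-	-	-	G	-	-	-	T	-	-	-	-	-	-	T	-	-	-	-	G	-	G	-	-	-	-	-	G	-	-	T
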