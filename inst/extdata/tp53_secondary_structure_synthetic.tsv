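# p53risk TP53 per-residue secondary structure, schema_version=1
# SYNTHETIC reconstruction from published descriptions of the p53 core-domain
# crystal structure, collapsed to {helix, strand, turn, unknown}; not a
# verbatim DSSP export. Residues outside the crystallised core are unknown.
codon	secondary_structure
1	unknown
2	unknown
3	unknown
4	unknown
5	unknown
6	unknown
7	unknown
8	unknown
9	unknown
10	unknown
11	unknown
12	unknown
13	unknown
14	unknown
15	unknown
16	unknown
17	unknown
18	unknown
19	unknown
20	unknown
21	unknown
22	unknown
23	unknown
24	unknown
25	unknown
26	unknown
27	unknown
28	unknown
29	unknown
30	unknown
31	unknown
32	unknown
33	unknown
34	unknown
35	unknown
36	unknown
37	unknown
38	unknown
39	unknown
40	unknown
41	unknown
42	unknown
43	unknown
44	unknown
45	unknown
46	unknown
47	unknown
48	unknown
49	unknown
50	unknown
51	unknown
52	unknown
53	unknown
54	unknown
55	unknown
56	unknown
57	unknown
58	unknown
59	unknown
60	unknown
61	unknown
62	unknown
63	unknown
64	unknown
65	unknown
66	unknown
67	unknown
68	unknown
69	unknown
70	unknown
71	unknown
72	unknown
73	unknown
74	unknown
75	unknown
76	unknown
77	unknown
78	unknown
79	unknown
80	unknown
81	unknown
82	unknown
83	unknown
84	unknown
85	unknown
86	unknown
87	unknown
88	unknown
89	unknown
90	unknown
91	unknown
92	unknown
93	unknown
94	unknown
95	unknown
96	unknown
97	unknown
98	unknown
99	unknown
100	unknown
101	unknown
102	unknown
103	unknown
104	unknown
105	unknown
106	unknown
107	unknown
108	unknown
109	unknown
110	strand
111	strand
112	strand
113	turn
114	turn
115	turn
116	turn
117	unknown
118	unknown
119	unknown
120	turn
121	turn
122	turn
123	turn
124	strand
125	strand
126	strand
127	strand
128	turn
129	turn
130	turn
131	turn
132	strand
133	strand
134	strand
135	strand
136	turn
137	turn
138	turn
139	turn
140	turn
141	strand
142	strand
143	strand
144	strand
145	strand
146	strand
147	turn
148	turn
149	turn
150	turn
151	turn
152	turn
153	turn
154	turn
155	turn
156	strand
157	strand
158	strand
159	strand
160	strand
161	strand
162	strand
163	strand
164	turn
165	turn
166	turn
167	turn
168	turn
169	turn
170	turn
171	unknown
172	unknown
173	unknown
174	unknown
175	unknown
176	unknown
177	helix
178	helix
179	helix
180	helix
181	helix
182	turn
183	turn
184	turn
185	turn
186	turn
187	turn
188	turn
189	turn
190	turn
191	unknown
192	unknown
193	unknown
194	unknown
195	strand
196	strand
197	strand
198	strand
199	turn
200	turn
201	turn
202	turn
203	strand
204	strand
205	strand
206	strand
207	strand
208	turn
209	turn
210	turn
211	turn
212	turn
213	turn
214	strand
215	strand
216	strand
217	strand
218	strand
219	strand
220	turn
221	turn
222	turn
223	turn
224	turn
225	turn
226	turn
227	turn
228	turn
229	turn
230	strand
231	strand
232	strand
233	strand
234	strand
235	strand
236	turn
237	turn
238	turn
239	turn
240	turn
241	turn
242	turn
243	turn
244	unknown
245	unknown
246	unknown
247	unknown
248	unknown
249	unknown
250	unknown
251	strand
252	strand
253	strand
254	strand
255	strand
256	strand
257	strand
258	turn
259	turn
260	turn
261	turn
262	turn
263	turn
264	strand
265	strand
266	strand
267	strand
268	strand
269	strand
270	strand
271	strand
272	strand
273	strand
274	strand
275	turn
276	turn
277	turn
278	helix
279	helix
280	helix
281	helix
282	helix
283	helix
284	helix
285	helix
286	helix
287	helix
288	helix
289	helix
290	turn
291	turn
292	turn
293	turn
294	turn
295	turn
296	unknown
297	unknown
298	unknown
299	unknown
300	unknown
301	unknown
302	unknown
303	unknown
304	unknown
305	unknown
306	unknown
307	unknown
308	unknown
309	unknown
310	unknown
311	unknown
312	unknown
313	unknown
314	unknown
315	unknown
316	unknown
317	unknown
318	unknown
319	unknown
320	unknown
321	unknown
322	unknown
323	unknown
324	unknown
325	unknown
326	unknown
327	unknown
328	unknown
329	unknown
330	unknown
331	unknown
332	unknown
333	unknown
334	unknown
335	unknown
336	unknown
337	unknown
338	unknown
339	unknown
340	unknown
341	unknown
342	unknown
343	unknown
344	unknown
345	unknown
346	unknown
347	unknown
348	unknown
349	unknown
350	unknown
351	unknown
352	unknown
353	unknown
354	unknown
355	unknown
356	unknown
357	unknown
358	unknown
359	unknown
360	unknown
361	unknown
362	unknown
363	unknown
364	unknown
365	unknown
366	unknown
367	unknown
368	unknown
369	unknown
370	unknown
371	unknown
372	unknown
373	unknown
374	unknown
375	unknown
376	unknown
377	unknown
378	unknown
379	unknown
380	unknown
381	unknown
382	unknown
383	unknown
384	unknown
385	unknown
386	unknown
387	unknown
388	unknown
389	unknown
390	unknown
391	unknown
392	unknown
393	unknown
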