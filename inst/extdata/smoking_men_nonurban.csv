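age_group,year,prevalence_pct
20-24,2004,49.7
25-29,2004,55.7
30-34,2004,56.1
35-39,2004,55.4
40-44,2004,53.3
45-49,2004,53
50-54,2004,51.4
55-59,2004,46.6
60-64,2004,38.4
65-69,2004,30.7
70-74,2004,26.8
75-79,2004,23.7
20-24,2007,41.4
25-29,2007,50
30-34,2007,50.9
35-39,2007,51
40-44,2007,49.2
45-49,2007,48.3
50-54,2007,45.9
55-59,2007,42.1
60-64,2007,36
65-69,2007,27.1
70-74,2007,21.9
75-79,2007,18.6
20-24,2010,33.2
25-29,2010,43.2
30-34,2010,45.4
35-39,2010,43.4
40-44,2010,44.1
45-49,2010,41.4
50-54,2010,39.7
55-59,2010,36.1
60-64,2010,30.4
65-69,2010,23.9
70-74,2010,17.9
75-79,2010,13.7
20-24,2013,32.4
25-29,2013,42
30-34,2013,44.7
35-39,2013,44.8
40-44,2013,42.4
45-49,2013,41.7
50-54,2013,40.2
55-59,2013,39.3
60-64,2013,34.2
65-69,2013,27.1
70-74,2013,20.4
75-79,2013,14.1
20-24,2016,27.6
25-29,2016,36.7
30-34,2016,41.5
35-39,2016,42.5
40-44,2016,41.3
45-49,2016,40.4
50-54,2016,38.2
55-59,2016,37.9
60-64,2016,33.9
65-69,2016,27
70-74,2016,19.9
75-79,2016,14.1
20-24,2019,24
25-29,2019,32.8
30-34,2019,36.7
35-39,2019,39.1
40-44,2019,39.4
45-49,2019,38.1
50-54,2019,37
55-59,2019,34.9
60-64,2019,31.2
65-69,2019,26.9
70-74,2019,20.3
75-79,2019,12.9
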