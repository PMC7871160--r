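age_group,year,prevalence_pct
20-24,2004,44.8
25-29,2004,46.7
30-34,2004,52.1
35-39,2004,51.7
40-44,2004,51.6
45-49,2004,51
50-54,2004,49.4
55-59,2004,48.9
60-64,2004,38.2
65-69,2004,33.8
70-74,2004,25.2
75-79,2004,24.7
20-24,2007,40.9
25-29,2007,46.2
30-34,2007,45.1
35-39,2007,47.1
40-44,2007,46.2
45-49,2007,43.5
50-54,2007,44.6
55-59,2007,42.8
60-64,2007,36.6
65-69,2007,30.4
70-74,2007,21.2
75-79,2007,20.7
20-24,2010,29.9
25-29,2010,37.9
30-34,2010,41.1
35-39,2010,39.6
40-44,2010,39.1
45-49,2010,38.3
50-54,2010,37.9
55-59,2010,35.6
60-64,2010,29.7
65-69,2010,22.6
70-74,2010,20.4
75-79,2010,14.5
20-24,2013,29.8
25-29,2013,38.6
30-34,2013,39.8
35-39,2013,39.3
40-44,2013,37.9
45-49,2013,37.3
50-54,2013,39.2
55-59,2013,38.1
60-64,2013,33.9
65-69,2013,30.5
70-74,2013,20.1
75-79,2013,16.4
20-24,2016,25.8
25-29,2016,29.8
30-34,2016,31.2
35-39,2016,36
40-44,2016,35.3
45-49,2016,35.6
50-54,2016,35
55-59,2016,33.4
60-64,2016,33
65-69,2016,27.3
70-74,2016,21.6
75-79,2016,14.7
20-24,2019,20
25-29,2019,27
30-34,2019,30.5
35-39,2019,30.4
40-44,2019,34
45-49,2019,34.9
50-54,2019,35.2
55-59,2019,31.9
60-64,2019,30.8
65-69,2019,27.2
70-74,2019,21.9
75-79,2019,16.1
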