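age_group,year,prevalence_pct
20-24,2004,20.9
25-29,2004,21.1
30-34,2004,20.9
35-39,2004,18.4
40-44,2004,17.9
45-49,2004,16
50-54,2004,13
55-59,2004,10.8
60-64,2004,8.2
65-69,2004,5.9
70-74,2004,4.9
75-79,2004,3.8
20-24,2007,17.7
25-29,2007,19.6
30-34,2007,19.2
35-39,2007,18.7
40-44,2007,17.5
45-49,2007,16.2
50-54,2007,13.4
55-59,2007,10.4
60-64,2007,8.2
65-69,2007,6
70-74,2007,4.4
75-79,2007,2.8
20-24,2010,12.8
25-29,2010,16.6
30-34,2010,17.4
35-39,2010,16.4
40-44,2010,15.3
45-49,2010,14.4
50-54,2010,12
55-59,2010,9.2
60-64,2010,7.1
65-69,2010,4.9
70-74,2010,3.5
75-79,2010,2.3
20-24,2013,11.9
25-29,2013,14.5
30-34,2013,15.4
35-39,2013,16.9
40-44,2013,16.3
45-49,2013,14.9
50-54,2013,14
55-59,2013,11.4
60-64,2013,8.8
65-69,2013,6.5
70-74,2013,4.2
75-79,2013,3.2
20-24,2016,9
25-29,2016,12.4
30-34,2016,13.1
35-39,2016,13.9
40-44,2016,15.9
45-49,2016,14.3
50-54,2016,13.7
55-59,2016,11.3
60-64,2016,8.6
65-69,2016,6.5
70-74,2016,5
75-79,2016,2.8
20-24,2019,7.3
25-29,2019,9.7
30-34,2019,11.2
35-39,2019,11.9
40-44,2019,13.2
45-49,2019,14.1
50-54,2019,12.7
55-59,2019,11.3
60-64,2019,9.4
65-69,2019,7
70-74,2019,5
75-79,2019,2.9
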