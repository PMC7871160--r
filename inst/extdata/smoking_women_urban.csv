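age_group,year,prevalence_pct
20-24,2004,20.4
25-29,2004,22.5
30-34,2004,20.8
35-39,2004,19
40-44,2004,21.6
45-49,2004,22.3
50-54,2004,17.5
55-59,2004,15.1
60-64,2004,10.5
65-69,2004,8.8
70-74,2004,7.8
75-79,2004,6.3
20-24,2007,17.7
25-29,2007,19.1
30-34,2007,19.4
35-39,2007,20.7
40-44,2007,19.1
45-49,2007,21.5
50-54,2007,18.5
55-59,2007,14.2
60-64,2007,11.7
65-69,2007,8
70-74,2007,6.7
75-79,2007,4.7
20-24,2010,12.3
25-29,2010,16.4
30-34,2010,14.9
35-39,2010,15.4
40-44,2010,15.1
45-49,2010,16.5
50-54,2010,16
55-59,2010,13.4
60-64,2010,9.8
65-69,2010,7.1
70-74,2010,5
75-79,2010,4.3
20-24,2013,9.9
25-29,2013,14.8
30-34,2013,13
35-39,2013,14.6
40-44,2013,15
45-49,2013,14.1
50-54,2013,18
55-59,2013,16
60-64,2013,11.6
65-69,2013,8.4
70-74,2013,6.4
75-79,2013,4.9
20-24,2016,6.8
25-29,2016,10.6
30-34,2016,11
35-39,2016,11.4
40-44,2016,13.1
45-49,2016,14.4
50-54,2016,13.6
55-59,2016,13.1
60-64,2016,12.3
65-69,2016,10
70-74,2016,5.5
75-79,2016,3.8
20-24,2019,6.7
25-29,2019,8.8
30-34,2019,10.6
35-39,2019,10.3
40-44,2019,11.2
45-49,2019,13.9
50-54,2019,12.5
55-59,2019,11.9
60-64,2019,12
65-69,2019,9
70-74,2019,7.6
75-79,2019,3.9
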