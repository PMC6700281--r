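cag	onset_years
59	10.59
55	23.09
45	33.92
42	45.09
41	46.45
58	28.27
53	29.5
42	49.86
38	59.74
53	21.44
38	53.59
44	40.43
59	1
60	11.38
51	11.68
47	47.65
43	40.04
60	25.57
58	18.75
50	19.05
59	7.9
56	38.13
40	56.68
54	9.22
43	48.84
40	67
49	33.25
41	38.94
56	11.27
43	35.58
43	41.87
53	29.25
51	37.59
40	67.18
52	25.27
48	30.85
53	20.2
37	61.25
48	26.18
51	27.85
59	10.07
38	57.28
55	14.64
50	36.86
53	21.41
57	11.31
44	37.31
58	31.76
60	1.59
50	20.3
48	40.09
58	12.96
45	49.32
58	9.84
53	42.84
51	14.27
50	32.65
58	3.88
51	24.4
57	16.18
45	40.5
54	28.69
52	12.74
38	46.3
42	56.17
55	7.97
36	66.69
40	36.28
60	10.18
57	8.93
45	41.78
38	49.73
52	25.85
42	35.16
47	48.63
53	22.32
54	30.93
41	53.35
40	54.17
54	36.65
36	78.23
54	22.04
49	24.57
44	34.69
53	27.01
39	67.06
47	32.3
50	30.54
51	20.94
43	48.68
36	62.13
41	51.41
42	56.17
45	36.31
60	24.74
47	33.86
42	62.08
44	44.43
38	68.36
50	42.79
44	31.67
39	55.93
44	42.29
56	10.63
48	38.54
39	53.13
39	56.39
56	33.9
59	26.64
36	60.44
40	65.75
51	28.27
56	26.94
50	28.89
50	24.41
38	59.92
42	33.58
51	22.17
53	18.23
47	31.75
50	33.05
38	81.38
48	42.98
43	52.38
48	22.8
46	35.03
51	11.06
38	48.03
46	45.92
60	30.84
41	56.58
59	16.7
37	61.81
43	53.06
49	13.03
59	18.07
55	15.34
37	80.53
56	24.66
58	13.71
60	12.69
46	36.03
59	17.41
59	11.42
43	43.95
54	26.13
41	60.86
47	39.39
48	35.76
43	47.96
48	22.03
50	18.27
37	70.86
53	20.79
53	18.84
58	6.15
53	25.35
46	42.07
45	40.44
37	57.35
57	26.95
52	35.36
57	17.19
58	23.07
36	71.13
42	44.66
38	59.75
44	33.16
53	11.09
49	40.37
51	21.72
59	5.72
40	64.65
44	51.41
44	35.84
40	63.03
58	16.82
60	16.11
44	42.65
46	32.4
57	20.7
52	14.7
45	29.3
50	16.42
36	49.51
50	25.75
42	44.01
48	35.36
40	52.13
46	41.93
38	70.37
38	61.98
40	50.3
53	30.98
46	33.9
41	45.36
38	54.39
39	58.46
53	34.02
48	22.14
44	52.38
56	16.97
48	30.62
60	10.11
58	21.92
50	32.63
37	57.91
54	19.51
53	5.69
57	36.42
44	30.65
53	36.79
38	64.71
56	22.09
56	21.71
40	45.4
50	23.91
60	22.05
49	36.35
56	11.74
42	62.35
48	33.21
57	35.74
53	37.19
51	34.81
58	28.09
55	25.4
36	61.72
45	32.38
45	44.8
43	66.41
53	27.75
58	22.35
52	32.7
58	12.68
44	53.26
47	35.16
41	64.99
58	30.15
43	47.25
43	40.8
54	26.93
39	68.28
36	76.37
59	25.87
49	18.76
57	20.67
40	73.14
55	17.25
47	40.98
39	58.34
51	28.38
41	40.1
56	29.86
38	64.72
56	10.03
47	25.44
37	62.62
45	47.86
60	24.45
40	49.65
43	53.64
36	71.61
53	31.23
59	11.55
51	26.61
48	32.61
39	52.33
42	55.02
39	64.97
51	28.28
38	54.54
43	55.32
51	33.69
38	65.82
53	32.33
43	46.45
46	31.89
57	24.53
42	53.68
58	24.84
54	21.81
40	61.61
51	30.22
46	31.51
38	69.08
50	35.26
47	38.87
53	22.44
36	60.06
50	34.82
54	22.62
38	60.52
36	55.09
56	21.79
55	18.47
37	55.93
36	78.58
45	55.32
41	47.02
36	45.74
57	37.93
38	47.43
59	7.03
53	42.07
40	55.37
36	75.91
53	34.03
48	44.8
58	23.23
56	27.19
51	18.87
40	51.14
53	27.72
39	66.18
57	19.25
41	42.91
54	37.18
44	46.49
48	17.59
60	28.65
52	15.61
47	27.74
49	48.44
45	21.08
44	28.16
37	76.77
38	51.71
44	46.32
49	43.42
46	45.24
40	49.25
54	23.41
51	18.36
54	9.1
55	25.5
55	24
40	40.42
42	43.03
38	72.3
54	34.7
38	64.5
53	13.21
57	15.93
37	70.36
38	47.16
36	54.38
57	5.66
58	17.07
42	27.05
57	31.17
60	22.42
47	17.55
56	27.81
42	44.44
56	14.98
43	42.84
51	27.21
56	16.85
45	49.72
48	31.58
41	59.06
52	39.56
53	21.17
52	39.32
51	23.65
50	32.44
53	36.39
55	21.22
44	43.84
48	14.54
55	17.67
36	55.78
51	19.7
58	35.72
56	21.9
51	37.16
45	38.33
45	35.28
50	37.77
44	47.19
51	36.27
56	11.74
41	56.07
59	13.63
60	11.6
44	28.67
48	40.72
39	69.18
49	10.18
36	72.25
52	15.51
56	19.76
37	71.44
40	57.18
58	21.06
45	34.27
42	50.81
45	32.38
46	43.94
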