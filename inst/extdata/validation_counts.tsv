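lesion	valve	category	tp	fp	fn	ppv	sensitivity	f1
stenosis	aortic	no_evidence	113	0	1	100.0	99.1	1.00
stenosis	aortic	prosthetic	28	0	0	100.0	100.0	1.00
stenosis	aortic	sclerosis	28	1	0	96.6	100.0	0.98
stenosis	aortic	severity_detected	31	0	0	100.0	100.0	1.00
stenosis	aortic	mild	15	0	0	100.0	100.0	1.00
stenosis	aortic	mild_to_moderate	1	0	0	100.0	100.0	1.00
stenosis	aortic	moderate	8	0	0	100.0	100.0	1.00
stenosis	aortic	moderate_to_severe	0	0	0			
stenosis	aortic	severe	7	0	0	100.0	100.0	1.00
stenosis	aortic	very_severe	0	0	0			
stenosis	aortic	unknown_severity	0	0	0			
stenosis	mitral	no_evidence	135	0	0	100.0	100.0	1.00
stenosis	mitral	prosthetic	17	0	0	100.0	100.0	1.00
stenosis	mitral	severity_detected	48	0	0	100.0	100.0	1.00
stenosis	mitral	mild	7	0	0	100.0	100.0	1.00
stenosis	mitral	mild_to_moderate	7	0	0	100.0	100.0	1.00
stenosis	mitral	moderate	21	0	0	100.0	100.0	1.00
stenosis	mitral	moderate_to_severe	7	0	1	100.0	87.5	0.93
stenosis	mitral	severe	4	1	0	80.0	100.0	0.89
stenosis	mitral	very_severe	0	0	0			
stenosis	mitral	unknown_severity	1	0	0	100.0	100.0	1.00
stenosis	tricuspid	no_evidence	185	0	0	100.0	100.0	1.00
stenosis	tricuspid	prosthetic	10	0	0	100.0	100.0	1.00
stenosis	tricuspid	severity_detected	5	0	0	100.0	100.0	1.00
stenosis	tricuspid	mild	1	0	0	100.0	100.0	1.00
stenosis	tricuspid	mild_to_moderate	0	0	0			
stenosis	tricuspid	moderate	1	0	0	100.0	100.0	1.00
stenosis	tricuspid	moderate_to_severe	2	0	0	100.0	100.0	1.00
stenosis	tricuspid	severe	0	0	0			
stenosis	tricuspid	very_severe	0	0	0			
stenosis	tricuspid	unknown_severity	1	0	0	100.0	100.0	1.00
stenosis	pulmonic	no_evidence	159	2	2	98.8	98.8	0.99
stenosis	pulmonic	prosthetic	12	1	1	92.3	92.3	0.92
stenosis	pulmonic	severity_detected	25	1	1	96.2	96.2	0.96
stenosis	pulmonic	mild	18	0	1	100.0	94.7	0.97
stenosis	pulmonic	mild_to_moderate	4	0	0	100.0	100.0	1.00
stenosis	pulmonic	moderate	1	0	0	100.0	100.0	1.00
stenosis	pulmonic	moderate_to_severe	0	0	0			
stenosis	pulmonic	severe	1	0	0	100.0	100.0	1.00
stenosis	pulmonic	very_severe	1	0	0	100.0	100.0	1.00
stenosis	pulmonic	unknown_severity	2	1	0	50.0	100.0	0.67
regurgitation	aortic	no_evidence	109	0	0	100.0	100.0	1.00
regurgitation	aortic	prosthetic	28	0	0	100.0	100.0	1.00
regurgitation	aortic	sclerosis	0	0	0			
regurgitation	aortic	severity_detected	63	0	0	100.0	100.0	1.00
regurgitation	aortic	trace	26	0	0	100.0	100.0	1.00
regurgitation	aortic	trace_to_mild	0	0	0			
regurgitation	aortic	mild	23	0	0	100.0	100.0	1.00
regurgitation	aortic	mild_to_moderate	7	0	0	100.0	100.0	1.00
regurgitation	aortic	moderate	5	0	0	100.0	100.0	1.00
regurgitation	aortic	moderate_to_severe	1	0	0	100.0	100.0	1.00
regurgitation	aortic	severe	1	0	0	100.0	100.0	1.00
regurgitation	aortic	very_severe	0	0	0			
regurgitation	aortic	unknown_severity	0	0	0			
regurgitation	mitral	no_evidence	60	0	0	100.0	100.0	1.00
regurgitation	mitral	prosthetic	17	0	0	100.0	100.0	1.00
regurgitation	mitral	severity_detected	123	0	0	100.0	100.0	1.00
regurgitation	mitral	trace	47	0	0	100.0	100.0	1.00
regurgitation	mitral	trace_to_mild	2	0	1	100.0	66.7	0.80
regurgitation	mitral	mild	35	1	0	97.2	100.0	0.99
regurgitation	mitral	mild_to_moderate	15	0	0	100.0	100.0	1.00
regurgitation	mitral	moderate	13	0	1	100.0	92.9	0.96
regurgitation	mitral	moderate_to_severe	3	0	0	100.0	100.0	1.00
regurgitation	mitral	severe	5	1	0	83.3	100.0	0.91
regurgitation	mitral	very_severe	0	0	0			
regurgitation	mitral	unknown_severity	0	0	0			
regurgitation	tricuspid	no_evidence	41	0	0	100.0	100.0	1.00
regurgitation	tricuspid	prosthetic	10	0	0	100.0	100.0	1.00
regurgitation	tricuspid	severity_detected	149	0	0	100.0	100.0	1.00
regurgitation	tricuspid	trace	46	0	1	100.0	97.9	0.99
regurgitation	tricuspid	trace_to_mild	2	1	0	66.7	100.0	0.80
regurgitation	tricuspid	mild	43	0	0	100.0	100.0	1.00
regurgitation	tricuspid	mild_to_moderate	22	0	0	100.0	100.0	1.00
regurgitation	tricuspid	moderate	19	0	0	100.0	100.0	1.00
regurgitation	tricuspid	moderate_to_severe	5	0	1	100.0	83.3	0.91
regurgitation	tricuspid	severe	10	1	0	90.9	100.0	0.95
regurgitation	tricuspid	very_severe	0	0	0			
regurgitation	tricuspid	unknown_severity	0	0	0			
regurgitation	pulmonic	no_evidence	121	0	1	100.0	99.2	1.00
regurgitation	pulmonic	prosthetic	12	1	1	92.3	92.3	0.92
regurgitation	pulmonic	severity_detected	64	2	1	97.0	98.5	0.98
regurgitation	pulmonic	trace	24	0	1	100.0	96.0	0.98
regurgitation	pulmonic	trace_to_mild	0	0	0			
regurgitation	pulmonic	mild	28	1	0	96.6	100.0	0.98
regurgitation	pulmonic	mild_to_moderate	3	0	0	100.0	100.0	1.00
regurgitation	pulmonic	moderate	6	0	0	100.0	100.0	1.00
regurgitation	pulmonic	moderate_to_severe	1	0	0	100.0	100.0	1.00
regurgitation	pulmonic	severe	2	1	0	66.7	100.0	0.80
regurgitation	pulmonic	very_severe	0	0	0			
regurgitation	pulmonic	unknown_severity	0	0	0			
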