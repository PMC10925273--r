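mutation	cation	leg_bound	leg_bound_err	leg_unbound	leg_unbound_err	printed_ddg	printed_err	label_bound	label_unbound	role	note
D59C	Na+	127.7	0.1	117.2	0.2	10.5	0.3	dG_mutation,Na+-bound	dG_mutation,Na+-unbound	Na+ binding	
D55C	Na+	132.9	0.2	124.3	0.2	8.6	0.4	dG_mutation,Na+-bound	dG_mutation,Na+-unbound	Na+ binding	results text prints 8.6 +/- 0.3; table prints +/- 0.4
T121A	Na+	22.5	0.1	15.89	0.03	6.7	0.1	dG_mutation,Na+-bound	dG_mutation,Na+-unbound	Na+ binding	printed ddG 6.7 vs legs 22.5 - 15.89 = 6.61
D55C	H+	126.2	0.1	124.2	0.1	2.0	0.2	dG_mutation,Asp59-H	dG_mutation,Asp59-	protonation of Asp59	
D59C	H+	117.2	0.2	122.2	0.3	5.1	0.4	dG_mutation,Asp59-H	dG_mutation,Asp59-	protonation of Asp55 (printed labels name Asp59)	discussion prints 5.0 +/- 0.4; legs per printed bound/unbound roles give -5.0
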