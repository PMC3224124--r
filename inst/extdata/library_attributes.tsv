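tissue	library_id	orientation	ests	unique_clones	source
stressed_leaf	10208	both	24400	21499	this_study
stressed_berry	12435	both	21384	18963	this_study
leaf	12752	both	2669	1465	public
leaf	12753	both	2051	1104	public
leaf	12948	both	2248	1441	public
leaf	12949	both	1146	739	public
leaf	14446	5	528	528	public
berry	4059	both	105	96	public
berry	8669	3	1989	1989	public
berry	8670	3	3268	3267	public
berry	8671	both	96	96	public
berry	11063	3	623	623	public
berry	11064	3	1691	1691	public
berry	12754	both	4429	2339	public
berry	13015	both	3414	1955	public
berry	13016	both	3836	2155	public
berry	13017	both	3558	1911	public
berry	14444	5	1743	1743	public
berry	20043	n.d.	4053	4053	public
berry	20044	n.d.	3035	3035	public
root	14445	5	1555	1555	public
root	16696	n.d.	102	102	public
stressed_root	22274	5	16452	16452	this_study
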