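pos	ref	alt	status
3243	A	G	confirmed
8993	T	G	confirmed
9176	T	C	confirmed
10191	T	C	confirmed
13513	G	A	confirmed
4216	T	C	reported
15928	G	A	reported
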