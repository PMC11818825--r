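pool	orientation	index	name	sequence
HMP	forward	1	27F	AGAGTTTGATCCTGGCTCAG
HMP	reverse	1	357R	TTACCGCGGCTGCTGGCAC
RapidSynth	forward	1	27F	AGAGTTTGATCCTGGCTCAG
RapidSynth	forward	2	27F-v2	AGRGTTTGATCYTGGCTCAG
RapidSynth	forward	3	27F-v3	AGAGTTTGATCMTGGCTCAG
RapidSynth	forward	4	27F-v4	AGGGTTCGATTCTGGCTCAG
RapidSynth	forward	5	27F-v5	AGAGTTYGATCCTGGCTCAG
RapidSynth	forward	6	27F-v6	AGRGTTYGATYMTGGCTCAG
RapidSynth	forward	7	27F-v7	ARAGTTTGATCCTGGYTCAG
RapidSynth	forward	8	27F-v8	AGAGTTTGAKCCTGGCTCAG
RapidSynth	forward	9	27F-v9	AGAGTTTGATCCTGGCTTAG
RapidSynth	forward	10	27F-v10	AGAGTTTGATCCTGGCWCAG
RapidSynth	reverse	1	357R	TTACCGCGGCTGCTGGCAC
RapidSynth	reverse	2	357R-v2	TTACCGCGGCKGCTGGCAC
RapidSynth	reverse	3	357R-v3	TTACCGCGGCTGCTGRCAC
RapidSynth	reverse	4	357R-v4	TTACCGCRGCTGCTGGCAC
RapidSynth	reverse	5	357R-v5	TTACCGCGGCTGGTGGCAC
RapidSynth	reverse	6	357R-v6	TTACYGCGGCTGCTGGCAC
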