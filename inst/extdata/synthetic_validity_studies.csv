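id,r,n,source,frame_of_reference
S0001,0.2097,37,non_journal,non_contextualized
S0002,0.173,97,journal,non_contextualized
S0003,0.0209,88,non_journal,contextualized
S0004,0.012,1013,non_journal,non_contextualized
S0005,0.0741,46,journal,non_contextualized
S0006,0.1328,144,non_journal,non_contextualized
S0007,0.0769,42,journal,non_contextualized
S0008,-0.3301,43,non_journal,non_contextualized
S0009,0.1108,143,non_journal,non_contextualized
S0010,0.3636,61,journal,contextualized
S0011,0.3397,130,non_journal,contextualized
S0012,0.0473,94,non_journal,non_contextualized
S0013,0.177,82,journal,non_contextualized
S0014,0.2249,30,journal,non_contextualized
S0015,0.0887,51,non_journal,non_contextualized
S0016,0.1905,149,non_journal,non_contextualized
S0017,0.1311,130,journal,non_contextualized
S0018,0.0987,388,journal,contextualized
S0019,0.0913,324,journal,non_contextualized
S0020,0.1134,125,journal,contextualized
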