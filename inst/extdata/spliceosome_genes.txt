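# Curated stand-in list of 42 core spliceosome genes (U1, U2, U4/U6 and U5
# snRNP components).  Replace with any newline-delimited gene list.
SNRNP200
PRPF8
EFTUD2
SNRNP40
PRPF6
DDX23
CD2BP2
TXNL4A
SNRNP70
SNRPA
SNRPC
SF3A1
SF3A2
SF3A3
SF3B1
SF3B2
SF3B3
SF3B4
SF3B5
SF3B6
SNRPA1
SNRPB2
U2AF1
U2AF2
PRPF3
PRPF4
PRPF31
SNU13
SART1
SART3
USP39
PRPF38A
SNRPB
SNRPD1
SNRPD2
SNRPD3
SNRPE
SNRPF
SNRPG
LSM2
LSM4
LSM8
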