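A C D E F G H I K L M N P Q R S T V W Y
A 0.0215 0.0016 0.0022 0.0030 0.0016 0.0058 0.0011 0.0032 0.0033 0.0044 0.0013 0.0019 0.0022 0.0019 0.0023 0.0063 0.0037 0.0051 0.0004 0.0013
C 0.0016 0.0119 0.0004 0.0004 0.0005 0.0008 0.0002 0.0011 0.0005 0.0016 0.0004 0.0004 0.0004 0.0003 0.0004 0.0010 0.0009 0.0014 0.0001 0.0003
D 0.0022 0.0004 0.0213 0.0049 0.0008 0.0025 0.0010 0.0012 0.0024 0.0015 0.0005 0.0037 0.0012 0.0016 0.0016 0.0028 0.0019 0.0013 0.0002 0.0006
E 0.0030 0.0004 0.0049 0.0161 0.0009 0.0019 0.0014 0.0012 0.0041 0.0020 0.0007 0.0022 0.0014 0.0035 0.0027 0.0030 0.0020 0.0017 0.0003 0.0009
F 0.0016 0.0005 0.0008 0.0009 0.0183 0.0012 0.0008 0.0030 0.0009 0.0054 0.0012 0.0008 0.0005 0.0005 0.0009 0.0012 0.0012 0.0026 0.0008 0.0042
G 0.0058 0.0008 0.0025 0.0019 0.0012 0.0378 0.0010 0.0014 0.0025 0.0021 0.0007 0.0029 0.0014 0.0014 0.0017 0.0038 0.0022 0.0018 0.0004 0.0008
H 0.0011 0.0002 0.0010 0.0014 0.0008 0.0010 0.0093 0.0006 0.0012 0.0010 0.0004 0.0014 0.0005 0.0010 0.0012 0.0011 0.0007 0.0006 0.0002 0.0015
I 0.0032 0.0011 0.0012 0.0012 0.0030 0.0014 0.0006 0.0184 0.0016 0.0114 0.0025 0.0010 0.0010 0.0009 0.0012 0.0017 0.0027 0.0120 0.0004 0.0014
K 0.0033 0.0005 0.0024 0.0041 0.0009 0.0025 0.0012 0.0016 0.0161 0.0025 0.0009 0.0024 0.0016 0.0031 0.0062 0.0031 0.0023 0.0019 0.0003 0.0010
L 0.0044 0.0016 0.0015 0.0020 0.0054 0.0021 0.0010 0.0114 0.0025 0.0371 0.0049 0.0014 0.0014 0.0016 0.0024 0.0024 0.0033 0.0095 0.0007 0.0022
M 0.0013 0.0004 0.0005 0.0007 0.0012 0.0007 0.0004 0.0025 0.0009 0.0049 0.0040 0.0005 0.0004 0.0007 0.0008 0.0009 0.0010 0.0023 0.0002 0.0006
N 0.0019 0.0004 0.0037 0.0022 0.0008 0.0029 0.0014 0.0010 0.0024 0.0014 0.0005 0.0141 0.0009 0.0015 0.0020 0.0031 0.0022 0.0012 0.0002 0.0007
P 0.0022 0.0004 0.0012 0.0014 0.0005 0.0014 0.0005 0.0010 0.0016 0.0014 0.0004 0.0009 0.0191 0.0008 0.0010 0.0017 0.0014 0.0012 0.0001 0.0005
Q 0.0019 0.0003 0.0016 0.0035 0.0005 0.0014 0.0010 0.0009 0.0031 0.0016 0.0007 0.0015 0.0008 0.0073 0.0025 0.0019 0.0014 0.0012 0.0002 0.0007
R 0.0023 0.0004 0.0016 0.0027 0.0009 0.0017 0.0012 0.0012 0.0062 0.0024 0.0008 0.0020 0.0010 0.0025 0.0178 0.0023 0.0018 0.0016 0.0003 0.0009
S 0.0063 0.0010 0.0028 0.0030 0.0012 0.0038 0.0011 0.0017 0.0031 0.0024 0.0009 0.0031 0.0017 0.0019 0.0023 0.0126 0.0047 0.0024 0.0003 0.0010
T 0.0037 0.0009 0.0019 0.0020 0.0012 0.0022 0.0007 0.0027 0.0023 0.0033 0.0010 0.0022 0.0014 0.0014 0.0018 0.0047 0.0125 0.0036 0.0003 0.0009
V 0.0051 0.0014 0.0013 0.0017 0.0026 0.0018 0.0006 0.0120 0.0019 0.0095 0.0023 0.0012 0.0012 0.0012 0.0016 0.0024 0.0036 0.0196 0.0004 0.0015
W 0.0004 0.0001 0.0002 0.0003 0.0008 0.0004 0.0002 0.0004 0.0003 0.0007 0.0002 0.0002 0.0001 0.0002 0.0003 0.0003 0.0003 0.0004 0.0065 0.0009
Y 0.0013 0.0003 0.0006 0.0009 0.0042 0.0008 0.0015 0.0014 0.0010 0.0022 0.0006 0.0007 0.0005 0.0007 0.0009 0.0010 0.0009 0.0015 0.0009 0.0102
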