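aa	chi1	chi2	chi3	chi4	probability
G	NA	NA	NA	NA	1.00
A	NA	NA	NA	NA	1.00
S	62	NA	NA	NA	0.48
S	-65	NA	NA	NA	0.29
S	-177	NA	NA	NA	0.22
C	-65	NA	NA	NA	0.50
C	-177	NA	NA	NA	0.26
C	62	NA	NA	NA	0.23
T	62	NA	NA	NA	0.49
T	-65	NA	NA	NA	0.43
T	-175	NA	NA	NA	0.07
V	175	NA	NA	NA	0.73
V	-60	NA	NA	NA	0.20
V	64	NA	NA	NA	0.06
L	-65	175	NA	NA	0.59
L	177	65	NA	NA	0.29
L	-172	154	NA	NA	0.02
I	-65	170	NA	NA	0.60
I	62	170	NA	NA	0.15
I	-57	-60	NA	NA	0.13
P	30	-35	NA	NA	0.44
P	-29	33	NA	NA	0.43
M	-65	175	75	NA	0.20
M	-65	-65	-70	NA	0.19
M	-177	180	75	NA	0.10
M	-65	175	180	NA	0.10
F	-65	-85	NA	NA	0.44
F	-177	80	NA	NA	0.33
F	62	90	NA	NA	0.13
Y	-65	-85	NA	NA	0.43
Y	-177	80	NA	NA	0.34
Y	62	90	NA	NA	0.13
W	-65	95	NA	NA	0.32
W	-177	-105	NA	NA	0.18
W	-177	90	NA	NA	0.16
W	62	-90	NA	NA	0.11
H	-65	-70	NA	NA	0.29
H	-65	165	NA	NA	0.13
H	-177	-165	NA	NA	0.13
H	62	-75	NA	NA	0.13
D	-65	-15	NA	NA	0.51
D	-177	0	NA	NA	0.21
D	62	-15	NA	NA	0.16
N	-65	-20	NA	NA	0.39
N	-177	-60	NA	NA	0.14
N	62	-75	NA	NA	0.14
E	-65	-177	-10	NA	0.27
E	-177	180	0	NA	0.24
E	-65	-65	-40	NA	0.17
Q	-65	-177	-25	NA	0.27
Q	-177	180	20	NA	0.16
Q	-65	-65	-40	NA	0.14
K	-65	180	180	180	0.25
K	180	180	180	180	0.18
K	-65	180	180	-65	0.08
K	-65	-65	180	180	0.06
R	-65	180	180	180	0.12
R	180	180	180	180	0.09
R	-65	180	65	85	0.08
R	-65	-65	180	180	0.07
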