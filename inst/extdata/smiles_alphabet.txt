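0
1
2
3
4
5
6
7
8
9
A
B
C
D
E
F
G
H
I
K
L
M
N
O
P
R
S
T
U
V
W
X
Y
Z
a
b
c
e
g
i
l
n
o
p
r
s
t
u
#
%
(
)
+
-
.
/
=
@
[
\
]
:
*
$
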