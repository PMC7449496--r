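name,delta_v_half,delta_slope,rel_density,complete_block,density_se,note
I204F,14.8,0,1.0,0,,activation shift as reported; density not reported so a neutral 1.0 placeholder is used
F279I,0,0,0.68,0,,32% current-density reduction as reported; kinetic deltas not reported
P197S,0,0,0.17,0,,fractional current density as reported; kinetic deltas not reported
R192C,0,0,0.21,0,,fractional current density as reported
T104I,0,0,0.22,0,,fractional current density as reported
I227L,0,0,0.22,0,,fractional current density as reported
C136F,0,0,0.23,0,,fractional current density as reported
V162M,0,0,0.24,0,,fractional current density as reported
V215G,0,0,0.33,0,,fractional current density as reported
Q107H,0,0,0.36,0,,fractional current density as reported
V241I,0,0,0.44,0,,fractional current density as reported
K218E,0,0,0.46,0,,fractional current density as reported
R195Q,0,0,0.49,0,,fractional current density as reported
T144A,0,0,0.5,0,,fractional current density as reported
A150T,0,0,0.58,0,,fractional current density as reported
M210I,0,0,0.63,0,,fractional current density as reported
E146K,0,0,0.65,0,,fractional current density as reported
T169M,0,0,0.65,0,,fractional current density as reported
V133I,0,0,0.67,0,,fractional current density as reported
T153M,0,0,0.67,0,,fractional current density as reported
L187P,0,0,0.68,0,,fractional current density as reported
F127L,0,0,0.8,0,,fractional current density as reported
V129I,0,0,0.83,0,,fractional current density as reported
A150G,0,0,0.93,0,,fractional current density as reported
H105L,0,0,1.31,0,,gain-of-function fractional current density as reported
P197L,0,0,1.47,0,,gain-of-function fractional current density as reported
R109L,0,0,2.23,0,,gain-of-function fractional current density as reported
KCNQ1_block,0,0,,1,,exemplar of variants with unmeasurably small current (complete block)
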