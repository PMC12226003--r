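# Bunsen solubility coefficient constants for methane in water/seawater.
# Fit: ln(beta) = A1 + A2*(100/T) + A3*ln(T/100)
#                 + S * (B1 + B2*(T/100) + B3*(T/100)^2)
# with T in kelvin, S in permil; beta in L gas (STP) per L liquid per atm.
# Source: Wiesenburg, D.A. & Guinasso, N.L. Jr (1979) "Equilibrium
# solubilities of methane, carbon monoxide, and hydrogen in water and sea
# water", J. Chem. Eng. Data 24(4):356-360, Table VI (Bunsen coefficient
# column for CH4). Fitted range: 273-313 K, 0-40 permil.
A: [-67.1962, 99.1624, 27.9015]
B: [-0.072909, 0.041674, -0.0064603]
source: "Wiesenburg & Guinasso (1979) J. Chem. Eng. Data 24:356-360"
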