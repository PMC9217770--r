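# patient P001
# group PBI_CTL
# organ breast_contralateral
# type differential
# volume_cm3 600
0	300
0.5	200
1	80
1.5	20

# patient P001
# group PBI_CTL
# organ lungs_both
# type differential
# volume_cm3 2800
0	1400
1	900
2	400
3	100

# patient P001
# group PBI_CTL
# organ lung_ipsilateral
# type differential
# volume_cm3 1400
0	400
1	600
2	300
3	100

# patient P001
# group PBI_CTL
# organ lung_contralateral
# type differential
# volume_cm3 1400
0	1000
1	300
2	100

# patient P001
# group PBI_CTL
# organ thyroid
# type cumulative
# volume_cm3 20
# units percent
0	100
0.5	40
1	10
1.5	0

# patient P001
# group PBI_CTL
# organ esophagus
# type differential
# volume_cm3 35
0	20
0.5	10
1	5
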