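# Nominal CIELAB values for a 24-patch ColorChecker-classic-style chart
# (widely circulated manufacturer-nominal aim values; actual charts vary
# by production batch, so supply your own measured table for metrology).
# The six neutral patches of the bottom row are tagged as white-balance
# squares and excluded from the colour-error mean.
patch_id,role,L,a,b
dark_skin,color,37.99,13.56,14.06
light_skin,color,65.71,18.13,17.81
blue_sky,color,49.93,-4.88,-21.93
foliage,color,43.14,-13.10,21.91
blue_flower,color,55.11,8.84,-25.40
bluish_green,color,70.72,-33.40,-0.20
orange,color,62.66,36.07,57.10
purplish_blue,color,40.02,10.41,-45.96
moderate_red,color,51.12,48.24,16.25
purple,color,30.33,22.98,-21.59
yellow_green,color,72.53,-23.71,57.26
orange_yellow,color,71.94,19.36,67.86
blue,color,28.78,14.18,-50.30
green,color,55.26,-38.34,31.37
red,color,42.10,53.38,28.19
yellow,color,81.73,4.04,79.82
magenta,color,51.94,49.99,-14.57
cyan,color,51.04,-28.63,-28.64
white,white_balance,96.54,-0.43,1.19
neutral_8,white_balance,81.26,-0.64,-0.34
neutral_6_5,white_balance,66.77,-0.73,-0.50
neutral_5,white_balance,50.87,-0.15,-0.27
neutral_3_5,white_balance,35.66,-0.42,-1.23
black,white_balance,20.46,-0.08,-0.97
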