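# SYNTHETIC stand-in for an 18-colour + 12-white-balance patch chart
# (RezChecker-style configuration). The manufacturer's reference values
# are not redistributable, so the colour rows reuse nominal classic-chart
# aims and the white-balance rows are an even L* ramp; replace with your
# chart's measured table for real metrology.
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
wb_01,white_balance,96.00,0.00,0.00
wb_02,white_balance,88.00,0.00,0.00
wb_03,white_balance,80.00,0.00,0.00
wb_04,white_balance,72.00,0.00,0.00
wb_05,white_balance,64.00,0.00,0.00
wb_06,white_balance,56.00,0.00,0.00
wb_07,white_balance,48.00,0.00,0.00
wb_08,white_balance,40.00,0.00,0.00
wb_09,white_balance,32.00,0.00,0.00
wb_10,white_balance,24.00,0.00,0.00
wb_11,white_balance,16.00,0.00,0.00
wb_12,white_balance,8.00,0.00,0.00
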