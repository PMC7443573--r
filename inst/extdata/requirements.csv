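category,nutrient,daily_amount
child_6_8m,energy,615
child_6_8m,protein,9.1
child_6_8m,fat,27
child_6_8m,calcium_absorbed,192
child_6_8m,iron_absorbed,0.79
child_6_8m,zinc,4.1
child_6_8m,thiamine,0.3
child_6_8m,riboflavin,0.4
child_6_8m,niacin,4
child_6_8m,magnesium,54
child_6_8m,vitamin_c,30
child_6_8m,retinol_equivalent,400
child_6_8m,folate,80
child_6_8m,vitamin_b6,0.3
child_6_8m,vitamin_b12,0.7
child_6_8m,vitamin_d,5
child_6_8m,vitamin_e,2.7
child_6_8m,copper,0.24
child_6_8m,selenium,10
child_9_11m,energy,686
child_9_11m,protein,9.6
child_9_11m,fat,30
child_9_11m,calcium_absorbed,192
child_9_11m,iron_absorbed,0.93
child_9_11m,zinc,4.1
child_9_11m,thiamine,0.3
child_9_11m,riboflavin,0.4
child_9_11m,niacin,4
child_9_11m,magnesium,54
child_9_11m,vitamin_c,30
child_9_11m,retinol_equivalent,400
child_9_11m,folate,80
child_9_11m,vitamin_b6,0.3
child_9_11m,vitamin_b12,0.7
child_9_11m,vitamin_d,5
child_9_11m,vitamin_e,2.7
child_9_11m,copper,0.24
child_9_11m,selenium,10
child_12_23m,energy,894
child_12_23m,protein,10.9
child_12_23m,fat,35
child_12_23m,calcium_absorbed,240
child_12_23m,iron_absorbed,0.58
child_12_23m,zinc,4.1
child_12_23m,thiamine,0.5
child_12_23m,riboflavin,0.5
child_12_23m,niacin,6
child_12_23m,magnesium,60
child_12_23m,vitamin_c,30
child_12_23m,retinol_equivalent,400
child_12_23m,folate,150
child_12_23m,vitamin_b6,0.5
child_12_23m,vitamin_b12,0.9
child_12_23m,vitamin_d,5
child_12_23m,vitamin_e,5
child_12_23m,copper,0.3
child_12_23m,selenium,17
woman_NPNL,energy,2100
woman_NPNL,protein,46
woman_NPNL,fat,70
woman_NPNL,calcium_absorbed,480
woman_NPNL,iron_absorbed,1.46
woman_NPNL,zinc,4.9
woman_NPNL,thiamine,1.1
woman_NPNL,riboflavin,1.1
woman_NPNL,niacin,14
woman_NPNL,magnesium,220
woman_NPNL,vitamin_c,45
woman_NPNL,retinol_equivalent,500
woman_NPNL,folate,400
woman_NPNL,vitamin_b6,1.3
woman_NPNL,vitamin_b12,2.4
woman_NPNL,vitamin_d,5
woman_NPNL,vitamin_e,7.5
woman_NPNL,copper,0.9
woman_NPNL,selenium,26
woman_pregnant,energy,2385
woman_pregnant,protein,60
woman_pregnant,fat,79
woman_pregnant,calcium_absorbed,576
woman_pregnant,iron_absorbed,3
woman_pregnant,zinc,8.4
woman_pregnant,thiamine,1.4
woman_pregnant,riboflavin,1.4
woman_pregnant,niacin,18
woman_pregnant,magnesium,220
woman_pregnant,vitamin_c,55
woman_pregnant,retinol_equivalent,800
woman_pregnant,folate,600
woman_pregnant,vitamin_b6,1.9
woman_pregnant,vitamin_b12,2.6
woman_pregnant,vitamin_d,5
woman_pregnant,vitamin_e,7.5
woman_pregnant,copper,1
woman_pregnant,selenium,28
woman_lactating,energy,2605
woman_lactating,protein,63
woman_lactating,fat,87
woman_lactating,calcium_absorbed,480
woman_lactating,iron_absorbed,1.15
woman_lactating,zinc,8.8
woman_lactating,thiamine,1.5
woman_lactating,riboflavin,1.6
woman_lactating,niacin,17
woman_lactating,magnesium,270
woman_lactating,vitamin_c,70
woman_lactating,retinol_equivalent,850
woman_lactating,folate,500
woman_lactating,vitamin_b6,2
woman_lactating,vitamin_b12,2.8
woman_lactating,vitamin_d,5
woman_lactating,vitamin_e,7.5
woman_lactating,copper,1.3
woman_lactating,selenium,35
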