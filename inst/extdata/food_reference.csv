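"food","label","food_group","health_value","protein_g","fat_g","carb_g","fibre_g","kcal"
"milk_full_fat","Full-fat milk","dairy",0.7,6.8,7,9.6,0,128.6
"milk_skimmed","Skimmed milk","dairy",0.75,7,0.6,10,0,73.4
"yoghurt_full_fat","Full-fat yoghurt","dairy",0.65,5,4.5,6,0,84.5
"yoghurt_skimmed","Skimmed yoghurt","dairy",0.7,5.5,0.5,7,0,54.5
"cheese","Cheese","dairy",0.45,7.5,9,0.5,0,113
"dairy_desserts","Dairy desserts","dairy",0.25,4,5,20,0,146
"fish","Fish","protein",0.95,18,5,0,0,117
"fish_fingers","Breaded fish","protein",0.45,13,9,15,0.6,193
"poultry","Poultry","protein",0.7,22,4,0,0,124
"red_meat","Red meat","protein",0.4,20,12,0,0,188
"ham","Ham","protein",0.3,9,3,0.5,0,65
"sausages","Sausages","protein",0.15,11,22,2,0,250
"eggs","Eggs","protein",0.7,6.5,5.5,0.5,0,77.5
"legumes","Legumes","protein",0.95,8,0.8,16,6.5,103.2
"nuts","Nuts","snacks",0.9,6,15,5,2.5,179
"seeds","Seeds","snacks",0.9,5.5,13,4,3,155
"vegetables_raw","Raw vegetables","vegetables",1,1.5,0.3,4,2,24.7
"vegetables_cooked","Cooked vegetables","vegetables",0.95,2,0.5,6,2.5,36.5
"potatoes","Boiled potatoes","starch",0.7,2.5,0.2,24,2.5,107.8
"fried_potatoes","Fried potatoes","starch",0.2,3.5,14,35,3,280
"rice","Rice","starch",0.65,4,0.5,40,0.8,180.5
"pasta","Pasta","starch",0.6,6,1,42,2,201
"wholemeal_bread","Whole meal bread","starch",0.95,5,1.5,22,4,121.5
"white_bread","White bread","starch",0.4,4.5,1.2,28,1.5,140.8
"breakfast_cereal","Breakfast cereal","starch",0.45,3,1,32,2,149
"porridge","Porridge","starch",0.85,5,2.5,24,3.5,138.5
"muesli","Muesli","starch",0.8,5.5,4,30,4.5,178
"pizza","Pizza","fast_food",0.15,11,12,35,2,292
"burgers","Burgers","fast_food",0.1,14,16,28,1.5,312
"savoury_pastries","Savoury pastries","fast_food",0.15,6,15,25,1,259
"fruit_fresh","Fresh fruit","fruit",1,0.8,0.3,14,2.4,61.9
"fruit_canned","Canned fruit","fruit",0.55,0.5,0.1,19,1.5,78.9
"dried_fruit","Dried fruit","fruit",0.7,1,0.3,27,3,114.7
"fruit_juice","Fruit juice","drinks",0.4,0.5,0.1,11,0.2,46.9
"sweetened_drinks","Sweetened drinks","drinks",0.05,0,0,11,0,44
"diet_drinks","Diet drinks","drinks",0.3,0,0,0.5,0,3
"water","Water","drinks",1,0,0,0.1,0,0.4
"tea","Tea","drinks",0.8,0.1,0,0.3,0,1.6
"honey","Honey","sweets",0.6,0.1,0,17,0,68.4
"jam","Jam","sweets",0.3,0.1,0,14,0.2,56.4
"chocolate","Chocolate","sweets",0.2,2,8,15,1,140
"candy","Candy","sweets",0.05,0,0.2,20,0,81.8
"cake","Cake","sweets",0.15,3,9,30,0.8,213
"biscuits","Biscuits","sweets",0.15,2,6,18,0.6,134
"ice_cream","Ice cream","sweets",0.2,2.5,7,16,0.3,137
"crisps","Crisps","snacks",0.1,2,10,15,1.2,158
"ketchup","Ketchup","condiments",0.25,0.3,0.1,6,0.1,26.1
"mayonnaise","Mayonnaise","condiments",0.15,0.2,12,1,0,112.8
"butter","Butter","fats",0.3,0.1,8,0.1,0,72.8
"olive_oil","Olive oil","fats",0.85,0,10,0,0,90
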