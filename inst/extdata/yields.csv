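item,label,land_type,account,average_yield,energy_footprint_density,convert_coefficient,unit
grain,"grains (grains, tubers, beans)",croplands,biological,5453.472,,,kg
oil,oil,croplands,biological,2189.756,,,kg
vegetables,vegetables and edible fungi,croplands,biological,28912.615,,,kg
sugarcane,sugarcane,croplands,biological,46910.696,,,kg
tobacco,tobacco,croplands,biological,2112.329,,,kg
tea,tea,forests,biological,804.813,,,kg
garden_fruit,garden fruit,forests,biological,2459.02,,,kg
cocoons,cocoons,forests,biological,600,,,kg
meat,"meat (cattle, sheep, pigs, poultry, rabbits)",grazing_lands,biological,5592.36,,,kg
milk,"milk (milk, sheep's milk)",grazing_lands,biological,494.10,,,kg
eggs,eggs,grazing_lands,biological,1151.27,,,kg
aquatic_products,"aquatic products (fish, shrimp and crabs, shellfish, algae)",fishing_grounds,biological,1475.079,,,kg
raw_coal,raw coal,carbon_capture_land,energy,,55,20.934,ton
natural_gas,natural gas,carbon_capture_land,energy,,93,18.003,ton
gasoline,gasoline,carbon_capture_land,energy,,93,43.124,ton
diesel,diesel,carbon_capture_land,energy,,93,42.705,ton
coke,coke,carbon_capture_land,energy,,55,28.47,ton
electricity,electricity,built_up,energy,,1000,11.84,1e4_kWh
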