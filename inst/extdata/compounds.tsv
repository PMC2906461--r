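name	formula	charge_note	role
cellobiose	C12H22O11	neutral	primary carbon and energy source (fermenter)
glucose	C6H12O6	neutral	hydrolysis equivalent
acetate	C2H4O2	acid form of acetate anion	fermentation product; carbon/energy source for secondary level
ethanol	C2H6O	neutral	trace fermentation product; electron donor
lactate	C3H6O3	acid form	minor fermentation product (little to none at steady state)
fumarate	C4H4O4	acid form	terminal electron acceptor (metal reducer)
succinate	C4H6O4	acid form	reduced acceptor product
malate	C4H6O5	acid form	fumarate hydration side product
hydrogen	H2	neutral gas	interspecies electron carrier
co2	CO2	dissolved/gas; carbonate speciation handled separately	oxidized reference product
water	H2O	neutral	solvent
ammonia	NH3	nitrogen reference state	N source
biomass	C4H7O1.5N	organic fraction of dry cell mass	cell material (104 g/mol with minerals)
sulfate	SO4	dianion; no degree of reduction assigned	terminal electron acceptor (sulfate reducer)
sulfide	H2S	total dissolved sulfide	reduced acceptor product (8 e-/mol via couple)
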