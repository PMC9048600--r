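word1,word2
movement,motion
movement,drift
divergence,separation
habitat,dwelling
species,taxon
forest,woodland
ocean,sea
river,stream
wetland,marsh
grassland,prairie
desert,barren
shrub,bush
fungus,mold
insect,bug
migration,journey
breeding,mating
predator,hunter
prey,quarry
nutrient,nourishment
temperature,warmth
precipitation,rainfall
drought,aridity
flood,inundation
growth,development
decay,decomposition
dormancy,quiescence
reproduction,propagation
dispersal,spread
extinction,disappearance
conservation,protection
restoration,recovery
disturbance,perturbation
diversity,variety
abundance,plenty
density,concentration
distribution,arrangement
range,extent
zone,belt
region,area
boundary,border
depth,profundity
soil,earth
seed,grain
flower,blossom
leaf,foliage
trait,characteristic
plant,flora
lake,pond
erosion,weathering
canopy,crown
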