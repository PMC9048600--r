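plant
trait
leaf
inflorescence
flower
root
stem
seed
fruit
soil
water
marine
forest
habitat
species
population
community
ecosystem
climate
tectonic
movement
divergence
plate
continental
erosion
sediment
river
lake
ocean
coastal
wetland
grassland
tundra
desert
canopy
shrub
moss
lichen
fungus
insect
pollination
migration
breeding
nesting
predator
prey
nutrient
carbon
nitrogen
phosphorus
mineral
temperature
humidity
precipitation
drought
flood
salinity
acidity
biomass
growth
decay
germination
dormancy
photosynthesis
respiration
transpiration
reproduction
dispersal
extinction
conservation
restoration
disturbance
succession
diversity
abundance
density
distribution
range
zone
region
layer
horizon
surface
depth
gradient
boundary
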