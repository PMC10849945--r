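# Coarse ecological grouping of raw habitat labels. Edit freely; any
# habitat not listed here maps to "Other".
human gut: Human gut
human faeces: Human gut
human oral: Human oral
saliva: Human oral
human skin: Human skin
marine: Marine
seawater: Marine
ocean: Marine
freshwater: Non-marine aquatic
groundwater: Non-marine aquatic
lake: Non-marine aquatic
animal gut: Animal gut
mouse gut: Animal gut
pig gut: Animal gut
soil: Soil
rhizosphere: Plant associated
phyllosphere: Plant associated
plant: Plant associated
wastewater: Anthropogenic
bioreactor: Anthropogenic
built environment: Anthropogenic
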