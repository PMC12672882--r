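criterion,description
Access points,"Number of access points; shortcuts connecting areas; pathway availability and quality"
Pathways,"Number and quality of pathways"
Facilities for different activities,"Number and quality of equipment for physical and social activities"
Open space,"Quality and provision of open space"
Amenities,"Seating, litter bins, dog bins, lighting, public art or installations"
Natural features,"Quantity and quality of vegetation (trees, flowers, plants) and water features"
Sunlight,"Moderate natural light exposure"
Incivilities,"Signs of disorder, including litter, alcohol debris, graffiti, vandalism, dog mess"
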