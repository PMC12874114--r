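# MNPS-OA diet-level scoring profiles, one block per model variant.
#
# Reference daily values (rdv) and creditable caps for the nine encourage
# items, and rdv for the limit items. Caps are given as the absolute
# creditable amount (cap_amount, same unit as the rdv); the scorer uses
# cap_amount / rdv as the cap fraction. The uncapped variants (wc, wel_wc)
# set cap_amount equal to the rdv. The without-energy-limit variants (wel,
# wel_wc) omit energy from the limit items. Sodium rdv is in grams.
original:
  limit_items:
    energy: {rdv: 2400}
    sugar: {rdv: 60}
    sodium: {rdv: 7.5}
  encourage_items:
    protein:       {rdv: 60,   cap_amount: 60}
    dietary_fiber: {rdv: 20,   cap_amount: 20}
    vitamin_d:     {rdv: 8.5,  cap_amount: 8.5}
    calcium:       {rdv: 750,  cap_amount: 389.4}
    fruits:        {rdv: 200,  cap_amount: 113}
    vegetables:    {rdv: 350,  cap_amount: 84.7}
    nuts:          {rdv: 75,   cap_amount: 75}
    legumes:       {rdv: 100,  cap_amount: 57}
    dairy:         {rdv: 130,  cap_amount: 55}
wel:
  limit_items:
    sugar: {rdv: 60}
    sodium: {rdv: 7.5}
  encourage_items:
    protein:       {rdv: 60,   cap_amount: 60}
    dietary_fiber: {rdv: 20,   cap_amount: 20}
    vitamin_d:     {rdv: 8.5,  cap_amount: 8.5}
    calcium:       {rdv: 750,  cap_amount: 389.4}
    fruits:        {rdv: 200,  cap_amount: 113}
    vegetables:    {rdv: 350,  cap_amount: 84.7}
    nuts:          {rdv: 75,   cap_amount: 75}
    legumes:       {rdv: 100,  cap_amount: 57}
    dairy:         {rdv: 130,  cap_amount: 55}
wc:
  limit_items:
    energy: {rdv: 2400}
    sugar: {rdv: 60}
    sodium: {rdv: 7.5}
  encourage_items:
    protein:       {rdv: 60,   cap_amount: 60}
    dietary_fiber: {rdv: 20,   cap_amount: 20}
    vitamin_d:     {rdv: 8.5,  cap_amount: 8.5}
    calcium:       {rdv: 750,  cap_amount: 750}
    fruits:        {rdv: 200,  cap_amount: 200}
    vegetables:    {rdv: 350,  cap_amount: 350}
    nuts:          {rdv: 75,   cap_amount: 75}
    legumes:       {rdv: 100,  cap_amount: 100}
    dairy:         {rdv: 130,  cap_amount: 130}
wel_wc:
  limit_items:
    sugar: {rdv: 60}
    sodium: {rdv: 7.5}
  encourage_items:
    protein:       {rdv: 60,   cap_amount: 60}
    dietary_fiber: {rdv: 20,   cap_amount: 20}
    vitamin_d:     {rdv: 8.5,  cap_amount: 8.5}
    calcium:       {rdv: 750,  cap_amount: 750}
    fruits:        {rdv: 200,  cap_amount: 200}
    vegetables:    {rdv: 350,  cap_amount: 350}
    nuts:          {rdv: 75,   cap_amount: 75}
    legumes:       {rdv: 100,  cap_amount: 100}
    dairy:         {rdv: 130,  cap_amount: 130}
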