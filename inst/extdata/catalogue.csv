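type_id,display_name,small_child_product,notes
armchairs,Armchairs,FALSE,
baby_changing_mat,Baby changing mat,TRUE,
baby_mattress,Baby mattress,TRUE,
baby_nests,Baby nests,TRUE,
baby_products_with_seat,Baby products with seat,TRUE,
bassinet,Bassinet,TRUE,
bean_bag,Bean bag,FALSE,
car_seat,Car seat,TRUE,
carry_cots,Carry cots,TRUE,
child_trailers_strollers,Child trailers and strollers,TRUE,includes pushchairs
divan,Divan,FALSE,
floor_cushion,Floor cushion,FALSE,
footboard,Footboard,FALSE,
headboard,Headboard,FALSE,
lightup_childrens_cushion,Light-up children's cushion,TRUE,
living_aids,Living aids,FALSE,
loose_stretch_covers,Loose and stretch covers,FALSE,
outdoor_furniture,Outdoor furniture,FALSE,
outdoor_furniture_upholstery,Outdoor furniture separate upholstery,FALSE,
padded_foot_stools,Padded foot stools,FALSE,
pet_beds,Pet beds,FALSE,
pillow,Pillow,FALSE,
play_mat,Play mat,TRUE,
playpens,Playpens,TRUE,
prams,Prams,TRUE,
scatter_cushion,Scatter cushion,FALSE,
seat_pad,Seat pad,FALSE,
separate_baby_upholstery,Separate baby upholstery,TRUE,
side_rails,Side rails,TRUE,
upholstered_bed_base,Upholstered bed base,FALSE,
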