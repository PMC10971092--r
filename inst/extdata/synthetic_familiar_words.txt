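a
about
add
all
and
animal
answer
apple
are
ball
box
boy
cat
circle
class
cost
count
day
dog
draw
each
eat
find
fish
five
four
girl
give
glass
good
green
has
have
how
if
in
is
it
left
line
long
look
many
more
most
much
name
new
nine
number
of
old
on
one
or
over
paper
pay
people
picture
put
read
red
right
run
sat
school
seven
shape
she
show
six
some
store
sum
table
take
tell
the
then
there
they
this
three
time
to
total
two
under
use
was
water
wear
what
when
which
who
will
with
write
year
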